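# Pattern analysis: standardization, PCA biplot quantities, Ward clustering
# of accessions, and per-group trait means.

#' Standardize a BLUP matrix
#'
#' Centers each trait column to mean zero and scales it to unit sample
#' standard deviation (denominator `n - 1`).  Traits measured in different
#' units (mm, g, dimensionless ratios) thereby contribute equally to
#' distances and principal components.
#'
#' @param bm a [build_blup_matrix()] result or a numeric matrix (accessions
#'   as rows).
#' @return A numeric matrix of z-scores with the input dimnames.
#' @export
standardize_blup <- function(bm) {
  x <- if (inherits(bm, "blup_matrix")) bm$values else as.matrix(bm)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    .stopf("constant column(s): %s", paste(colnames(x)[sds == 0], collapse = ", "))
  }
  z <- scale(x)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  z[]
}

#' Principal components of a standardized trait matrix
#'
#' Eigendecomposition of the trait correlation matrix of `z` (the covariance
#' of the standardized columns).  Scores are `z %*% V`; loadings are the
#' eigenvectors scaled by the square roots of their eigenvalues, so that a
#' biplot of scores and loadings reproduces the trait correlations.  Each
#' component's share of the total variation is reported in percent.
#'
#' Sign convention: within each component the loading of largest absolute
#' value is made positive (ties broken by the earliest trait), so results
#' are identical across platforms and eigensolvers.
#'
#' @param z a standardized matrix from [standardize_blup()].
#' @return A list of class `pca_result` with `scores` (accession x
#'   component), `loadings` (trait x component), `eigenvalues`, `pct_var`
#'   and `rotation` (the raw eigenvectors).
#' @export
pca_biplot <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2L || ncol(z) < 2L) .stopf("need >= 2 accessions and >= 2 traits")
  cm <- stats::cov(z)
  if (all(abs(cm) < 1e-300)) .stopf("rank-0 input: no variation to decompose")
  eg <- eigen(cm, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (j in seq_len(ncol(vecs))) {     # deterministic sign convention
    lead <- which.max(abs(vecs[, j]))
    if (vecs[lead, j] < 0) vecs[, j] <- -vecs[, j]
  }
  comp <- paste0("PC", seq_along(vals))
  dimnames(vecs) <- list(colnames(z), comp)
  scores <- z %*% vecs
  loadings <- sweep(vecs, 2L, sqrt(vals), `*`)
  structure(
    list(scores = scores, loadings = loadings, eigenvalues = vals,
         pct_var = 100 * vals / sum(vals), rotation = vecs),
    class = "pca_result")
}

#' Hierarchical clustering of accessions
#'
#' Agglomerative clustering of the rows of a standardized trait matrix using
#' Euclidean distance, cut to exactly `k` groups.  The default linkage is
#' Ward's minimum-variance criterion (on true Euclidean distances,
#' `stats::hclust` method `"ward.D2"`), the standard choice in germplasm
#' pattern analysis; other linkages can be requested.  Group ids are
#' relabelled 1..k in order of first accession appearance so they are
#' reproducible from the input row order.
#'
#' @param z a standardized matrix ([standardize_blup()]).
#' @param k number of groups, between 1 and the number of accessions.
#' @param linkage `"ward"` (default), `"complete"`, `"average"` or
#'   `"single"`.
#' @return A list of class `cluster_result` with `clusters` (named integer
#'   vector), `k`, `linkage`, `merge_history` (data.frame with columns
#'   `step`, `member1`, `member2`, `height`; negative members are
#'   singletons, positive refer to earlier merge steps, as in
#'   [stats::hclust()]) and the `hclust` object itself.
#' @export
cluster_accessions <- function(z, k, linkage = c("ward", "complete",
                                                 "average", "single")) {
  z <- as.matrix(z)
  linkage <- match.arg(linkage)
  n <- nrow(z)
  if (!.is_count(k) || k > n) .stopf("`k` must be an integer in 1..%d", n)
  method <- c(ward = "ward.D2", complete = "complete", average = "average",
              single = "single")[[linkage]]
  hc <- stats::hclust(stats::dist(z), method = method)
  raw <- stats::cutree(hc, k = k)
  # relabel groups by first appearance in row order
  first <- unique(raw)
  clusters <- stats::setNames(match(raw, first), rownames(z))
  merge_history <- data.frame(step = seq_len(nrow(hc$merge)),
                              member1 = hc$merge[, 1L],
                              member2 = hc$merge[, 2L],
                              height = hc$height)
  structure(
    list(clusters = clusters, k = as.integer(k), linkage = linkage,
         merge_history = merge_history, hclust = hc),
    class = "cluster_result")
}

#' Per-group trait means
#'
#' Arithmetic means of the BLUP accession means within each cluster group,
#' reported in the original trait units, together with group sizes.
#'
#' @param bm a [build_blup_matrix()] result (or numeric matrix with row
#'   names).
#' @param clusters a named group assignment covering every accession (e.g.
#'   `cluster_accessions()$clusters`).
#' @return A list of class `group_means` with `means` (group x trait
#'   matrix) and `sizes`.
#' @export
group_means <- function(bm, clusters) {
  x <- if (inherits(bm, "blup_matrix")) bm$values else as.matrix(bm)
  if (is.list(clusters) && !is.null(clusters$clusters)) {
    clusters <- clusters$clusters
  }
  unknown <- setdiff(names(clusters), rownames(x))
  if (length(unknown)) {
    .stopf("unknown accession(s) in assignment: %s",
           paste(unknown, collapse = ", "))
  }
  uncovered <- setdiff(rownames(x), names(clusters))
  if (length(uncovered)) {
    .stopf("assignment misses accession(s): %s",
           paste(uncovered, collapse = ", "))
  }
  g <- clusters[rownames(x)]
  groups <- sort(unique(g))
  means <- do.call(rbind, lapply(groups, function(gi) {
    colMeans(x[g == gi, , drop = FALSE])
  }))
  rownames(means) <- as.character(groups)
  structure(
    list(means = means,
         sizes = stats::setNames(as.integer(table(g)[as.character(groups)]),
                                 as.character(groups))),
    class = "group_means")
}

#' Pattern analysis of a BLUP accession x trait matrix
#'
#' The full pattern-analysis bundle: standardize the matrix, compute the
#' PCA biplot quantities, cluster accessions (Ward by default), cut at `k`
#' groups and summarize group trait means in original units.
#'
#' @inheritParams cluster_accessions
#' @param bm a [build_blup_matrix()] result.
#' @param k number of cluster groups.
#' @return An object of class `pattern_result` with fields `accessions`,
#'   `traits`, `scores`, `loadings`, `eigenvalues`, `pct_var`, `clusters`,
#'   `group_means`, `group_sizes`, `merge_history`, `linkage`, `k`.
#' @examples
#' ds <- demo_seed_dataset(seed = 1)
#' bm <- build_blup_matrix(ds, "across_years")
#' pattern_analysis(bm, k = 3)
#' @export
pattern_analysis <- function(bm, k = 3, linkage = "ward") {
  stopifnot(inherits(bm, "blup_matrix"))
  z <- standardize_blup(bm)
  pca <- pca_biplot(z)
  cl <- cluster_accessions(z, k = k, linkage = linkage)
  gm <- group_means(bm, cl$clusters)
  structure(
    list(accessions = bm$accessions, traits = bm$traits,
         scores = pca$scores, loadings = pca$loadings,
         eigenvalues = pca$eigenvalues, pct_var = pca$pct_var,
         clusters = cl$clusters, group_means = gm$means,
         group_sizes = gm$sizes, merge_history = cl$merge_history,
         linkage = cl$linkage, k = cl$k),
    class = "pattern_result")
}

#' @export
print.pattern_result <- function(x, ...) {
  cat(sprintf("<pattern_result> %d accessions x %d traits | %s linkage, k = %d\n",
              length(x$accessions), length(x$traits), x$linkage, x$k))
  cat(sprintf("  PC1 %.2f%%, PC2 %.2f%% of total variation\n",
              x$pct_var[1L], x$pct_var[2L]))
  cat("  group sizes:", paste(sprintf("%s:%d", names(x$group_sizes),
                                      x$group_sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Biplot of a pattern-analysis result
#'
#' Base-graphics display of accession scores on the first two components
#' with trait loading vectors, symbols by cluster group.  Presentation
#' helper only.
#'
#' @param x a `pattern_result`.
#' @param scale multiplier applied to loading vectors for legibility.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pattern_result <- function(x, scale = NULL, ...) {
  s <- x$scores[, 1:2, drop = FALSE]
  l <- x$loadings[, 1:2, drop = FALSE]
  scale <- scale %||% (0.8 * max(abs(s)) / max(abs(l)))
  graphics::plot(s, pch = x$clusters, col = x$clusters,
                 xlab = sprintf("PC1 (%.2f%%)", x$pct_var[1L]),
                 ylab = sprintf("PC2 (%.2f%%)", x$pct_var[2L]), ...)
  graphics::abline(h = 0, v = 0, col = "grey80", lty = 3)
  graphics::arrows(0, 0, l[, 1L] * scale, l[, 2L] * scale,
                   length = 0.08, col = "grey40")
  graphics::text(l[, 1L] * scale * 1.08, l[, 2L] * scale * 1.08,
                 rownames(l), cex = 0.8, col = "grey20")
  graphics::text(s, labels = rownames(s), pos = 3, cex = 0.7)
  invisible(x)
}
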