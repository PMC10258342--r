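# Correlation matrices with significance, and MANOVA sums of cross-products.

# Pearson correlation of columns of x against columns of y (or of x with
# itself), with two-sided p-values from t = r sqrt((n-2)/(1-r^2)) on n-2 df.
.cor_test_matrix <- function(x, y = NULL) {
  n <- nrow(x)
  if (n < 3L) .stopf("need >= 3 observations for correlation tests, got %d", n)
  square <- is.null(y)
  const_x <- apply(x, 2L, stats::sd) == 0
  if (any(const_x)) {
    .stopf("constant column(s): %s", paste(colnames(x)[const_x], collapse = ", "))
  }
  if (!square) {
    const_y <- apply(y, 2L, stats::sd) == 0
    if (any(const_y)) {
      .stopf("constant column(s): %s",
             paste(colnames(y)[const_y], collapse = ", "))
    }
  }
  r <- if (square) stats::cor(x) else stats::cor(x, y)
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  if (square) {
    diag(r) <- 1
    diag(p) <- NA_real_
  }
  stars <- matrix(.stars(p), nrow = nrow(p), dimnames = dimnames(r))
  structure(
    list(labels = rownames(r), col_labels = colnames(r), r = r, p = p,
         n = n, stars = stars, square = square),
    class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<correlation_matrix> %s (n = %d)\n",
              if (x$square) "symmetric" else
                sprintf("%d x %d", nrow(x$r), ncol(x$r)), x$n))
  disp <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
                 nrow = nrow(x$r), dimnames = dimnames(x$r))
  if (x$square) disp[upper.tri(disp, diag = TRUE)] <- ""
  print(disp, quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.correlation_matrix <- function(x, ...) {
  idx <- if (x$square) which(lower.tri(x$r), arr.ind = TRUE) else
    as.matrix(expand.grid(row = seq_len(nrow(x$r)), col = seq_len(ncol(x$r))))
  data.frame(var1 = rownames(x$r)[idx[, 1L]],
             var2 = colnames(x$r)[idx[, 2L]],
             r = x$r[idx], p = x$p[idx], stars = x$stars[idx],
             stringsAsFactors = FALSE)
}

#' Phenotypic correlations among traits
#'
#' Pairwise Pearson correlations of trait columns across accessions of a
#' BLUP-adjusted mean matrix, with two-sided p-values from the t transform
#' on `n - 2` degrees of freedom and significance stars at 0.05 (`*`) and
#' 0.01 (`**`).
#'
#' @param bm a [build_blup_matrix()] result (or a plain numeric matrix with
#'   accessions as rows and traits as columns).
#' @return An object of class `correlation_matrix` with elements `labels`,
#'   `r`, `p`, `n` and `stars`.
#' @export
phenotypic_correlation <- function(bm) {
  x <- if (inherits(bm, "blup_matrix")) bm$values else as.matrix(bm)
  .cor_test_matrix(x)
}

#' Trait-environment correlations
#'
#' Pearson correlations of each trait's BLUP accession means against numeric
#' site covariates (altitude, temperature summaries, ...), with the same
#' test conventions as [phenotypic_correlation()].
#'
#' @param bm a [build_blup_matrix()] result.
#' @param meta a [read_site_metadata()] table (or data.frame with an
#'   `accession` column) covering every accession in `bm`.
#' @param covariates names of metadata columns to correlate; defaults to all
#'   numeric columns.
#' @return A rectangular `correlation_matrix` (traits x covariates).
#' @export
env_correlation <- function(bm, meta, covariates = NULL) {
  stopifnot(inherits(bm, "blup_matrix"))
  if (!"accession" %in% names(meta)) .stopf("metadata lacks an 'accession' column")
  missing <- setdiff(bm$accessions, meta$accession)
  if (length(missing)) {
    .stopf("accession(s) missing from site metadata: %s",
           paste(missing, collapse = ", "))
  }
  covariates <- covariates %||% setdiff(names(meta), "accession")
  absent <- setdiff(covariates, names(meta))
  if (length(absent)) {
    .stopf("covariate(s) not in metadata: %s", paste(absent, collapse = ", "))
  }
  m <- meta[match(bm$accessions, meta$accession), covariates, drop = FALSE]
  .cor_test_matrix(bm$values, as.matrix(m))
}

#' Components-based phenotypic correlations (single year)
#'
#' Alternative phenotypic correlation estimator built from the multivariate
#' analogue of the expected mean squares: the genotypic covariance of a trait
#' pair is `(B/df_b - W/df_w)/nr` and the phenotypic covariance is its sum
#' with the residual covariance `W/df_w`, where `B` and `W` are the between-
#' and within-accession sums of cross-products ([sscp_strata()]).  Unlike the
#' default BLUP-mean route ([phenotypic_correlation()]) this uses replicate-
#' level information, but it admits no exact small-sample significance test,
#' so no p-values or stars are reported.  Defined for a single year.
#'
#' @param ds a [trait_dataset()].
#' @param traits trait names (>= 2); defaults to all.
#' @param year the year to analyse (may be omitted for one-year datasets).
#' @return A `correlation_matrix` with `p` and `stars` set to `NA`/`""`.
#' @export
phenotypic_correlation_components <- function(ds, traits = NULL, year = NULL) {
  stopifnot(inherits(ds, "trait_dataset"))
  if (is.null(year)) {
    if (length(ds$years) > 1L) .stopf("pass `year` for multi-year datasets")
    year <- ds$years
  }
  traits <- traits %||% ds$traits
  if (length(traits) < 2L) .stopf("need >= 2 traits")
  s <- sscp_strata(ds, traits, year = year)
  cov_e <- s$within / s$df_within
  cov_g <- (s$between / s$df_between - cov_e) / s$nr
  cov_p <- cov_g + cov_e
  d <- sqrt(diag(cov_p))
  if (any(d <= 0)) {
    .stopf("non-positive phenotypic variance for trait(s): %s",
           paste(s$labels[d <= 0], collapse = ", "))
  }
  r <- cov_p / tcrossprod(d)
  r <- pmin(pmax((r + t(r)) / 2, -1), 1)
  diag(r) <- 1
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  structure(
    list(labels = rownames(r), col_labels = colnames(r), r = r, p = p,
         n = length(unique(ds$accessions)),
         stars = matrix("", nrow(r), ncol(r), dimnames = dimnames(r)),
         square = TRUE),
    class = "correlation_matrix")
}

#' MANOVA sums of cross-products by stratum
#'
#' Decomposes the multi-trait cross-product matrix into an accession
#' (between) stratum and a residual (within) stratum after adjusting for the
#' fixed effects (the grand mean in a single year; year means across years).
#' On balanced data `between + within` equals the total adjusted SSCP.  The
#' analysis uses per-replicate trait vectors, so every trait must cover the
#' same (accession, year, replicate) cells.
#'
#' @param ds a [trait_dataset()].
#' @param traits trait names to include (>= 2); defaults to all traits.
#' @param year optional single year; omitted, all years are used and year
#'   means are removed as fixed effects.
#' @return An object of class `sscp_decomposition` with symmetric matrices
#'   `between` and `within` and degrees of freedom `df_between`, `df_within`.
#' @export
sscp_strata <- function(ds, traits = NULL, year = NULL) {
  stopifnot(inherits(ds, "trait_dataset"))
  traits <- traits %||% ds$traits
  if (length(traits) < 1L) .stopf("need at least one trait")
  r <- ds$records[ds$records$trait %in% traits, , drop = FALSE]
  if (!is.null(year)) r <- r[r$year == year, , drop = FALSE]
  if (nrow(r) == 0L) .stopf("no records for the requested traits/year")
  # wide replicate-level matrix: rows = (accession, year, replicate)
  key <- paste(r$accession, r$year, r$replicate, sep = "\r")
  wide <- tapply(r$value, list(key, factor(r$trait, levels = traits)), identity)
  if (anyNA(wide)) {
    bad <- unique(colnames(wide)[which(is.na(wide), arr.ind = TRUE)[, 2L]])
    .stopf("unequal record coverage across traits: %s",
           paste(bad, collapse = ", "))
  }
  parts <- do.call(rbind, strsplit(rownames(wide), "\r", fixed = TRUE))
  acc <- parts[, 1L]
  yr <- parts[, 2L]
  a <- length(unique(acc))
  if (a < 2L) .stopf("need >= 2 accessions")
  cell <- table(acc, yr)
  if (length(unique(as.integer(cell))) != 1L || any(cell == 0L)) {
    .stopf("unbalanced design: sums of cross-products need equal cell counts")
  }
  nl <- length(unique(yr))
  nr <- as.integer(cell[1L])
  n <- nrow(wide)
  # remove fixed effects: year means (reduces to the grand mean when nl = 1)
  year_means <- apply(wide, 2L, function(v) tapply(v, yr, mean))
  if (nl == 1L) year_means <- matrix(year_means, nrow = 1L,
                                     dimnames = list(unique(yr), traits))
  adj <- wide - year_means[yr, , drop = FALSE]
  acc_means <- apply(adj, 2L, function(v) tapply(v, acc, mean))
  grand <- colMeans(adj)  # zero by construction, kept for clarity
  dev <- sweep(acc_means, 2L, grand)
  between <- nl * nr * crossprod(dev)
  resid <- adj - acc_means[acc, , drop = FALSE]
  within <- crossprod(resid)
  structure(
    list(labels = traits, between = between, within = within,
         df_between = a - 1L, df_within = n - a - nl + 1L,
         nl = nl, nr = nr),
    class = "sscp_decomposition")
}

#' @export
print.sscp_decomposition <- function(x, ...) {
  cat(sprintf("<sscp_decomposition> %d traits | df between = %d, within = %d\n",
              length(x$labels), x$df_between, x$df_within))
  invisible(x)
}
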