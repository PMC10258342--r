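test_that("standardization centers and scales every trait column", {
  bm <- build_blup_matrix(demo_seed_dataset(seed = 3), "across_years")
  z <- standardize_blup(bm)
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_equal(unname(apply(z, 2L, sd)), rep(1, ncol(z)))
  # idempotence
  expect_equal(standardize_blup(z), z, tolerance = 1e-12)
  # the n-1 denominator: column (1,2,3) maps to (-1, 0, 1)
  expect_equal(unname(standardize_blup(cbind(a = 1:3, b = c(5, 1, 3)))[, "a"]),
               c(-1, 0, 1))
  expect_error(standardize_blup(cbind(a = c(1, 1, 1), b = 1:3)),
               "constant column\\(s\\): a")
})

test_that("PCA shares of variation behave in the known limits", {
  # two orthogonal standardized columns: isotropy, 50/50
  z <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1)) / sqrt(4 / 3)
  p <- pca_biplot(z)
  expect_equal(p$pct_var, c(50, 50))
  # duplicated trait: rank 1, 100/0
  z2 <- standardize_blup(cbind(a = c(1, 3, 2, 5), b = c(2, 6, 4, 10)))
  p2 <- pca_biplot(z2)
  expect_equal(p2$pct_var, c(100, 0), tolerance = 1e-10)
})

test_that("PCA matches an independent SVD route and reconstructs the input", {
  set.seed(42)
  z <- standardize_blup(matrix(rnorm(15 * 9), 15, 9,
                               dimnames = list(sprintf("A%02d", 1:15),
                                               paste0("t", 1:9))))
  p <- pca_biplot(z)
  # oracle: singular values of the centered matrix give the eigenvalues
  sv <- svd(z)
  expect_equal(p$eigenvalues, sv$d^2 / (nrow(z) - 1), tolerance = 1e-8)
  expect_equal(sum(p$pct_var), 100, tolerance = 1e-9)
  expect_true(all(diff(p$pct_var) <= 1e-12))
  # scores reproduce z through the rotation
  expect_equal(p$scores %*% t(p$rotation), z, tolerance = 1e-8)
  # score columns are mutually orthogonal
  g <- crossprod(p$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # loadings are eigenvectors scaled by sqrt(eigenvalue)
  expect_equal(p$loadings,
               sweep(p$rotation, 2L, sqrt(p$eigenvalues), `*`))
})

test_that("the sign convention makes results deterministic", {
  set.seed(5)
  z <- standardize_blup(matrix(rnorm(12 * 5), 12, 5,
                               dimnames = list(letters[1:12],
                                               paste0("t", 1:5))))
  p1 <- pca_biplot(z)
  # largest-magnitude loading of every component is positive
  for (j in seq_len(ncol(p1$rotation))) {
    expect_gt(p1$rotation[which.max(abs(p1$rotation[, j])), j], 0)
  }
  # negating the data flips scores but leaves loadings and shares fixed
  p2 <- pca_biplot(-z)
  expect_equal(p2$rotation, p1$rotation)
  expect_equal(p2$pct_var, p1$pct_var)
  expect_equal(p2$scores, -p1$scores)
})

test_that("row permutation permutes scores and clusters but nothing else", {
  bm <- build_blup_matrix(demo_seed_dataset(seed = 22), "across_years")
  z <- standardize_blup(bm)
  perm <- c(4:15, 1:3)
  p1 <- pca_biplot(z); p2 <- pca_biplot(z[perm, ])
  expect_equal(p2$scores, p1$scores[perm, ])
  expect_equal(p2$loadings, p1$loadings)
  expect_equal(p2$pct_var, p1$pct_var)
  c1 <- cluster_accessions(z, 3); c2 <- cluster_accessions(z[perm, ], 3)
  expect_equal(sort(c1$merge_history$height), sort(c2$merge_history$height))
  # same partition up to group relabelling
  expect_equal(adjusted_rand_index(c1$clusters[rownames(z)[perm]],
                                   c2$clusters), 1)
})

test_that("clustering limits: k = 1 and k = n", {
  z <- standardize_blup(build_blup_matrix(demo_seed_dataset(seed = 2),
                                          "across_years"))
  c1 <- cluster_accessions(z, 1)
  expect_true(all(c1$clusters == 1L))
  cn <- cluster_accessions(z, nrow(z))
  expect_equal(sort(unname(cn$clusters)), seq_len(nrow(z)))
  expect_error(cluster_accessions(z, 0), "`k` must be")
  expect_error(cluster_accessions(z, nrow(z) + 1), "`k` must be")
})

test_that("Ward merge heights never decrease and clustering is a pure function", {
  z <- standardize_blup(build_blup_matrix(demo_seed_dataset(seed = 2),
                                          "across_years"))
  cl <- cluster_accessions(z, 3)
  expect_true(all(diff(cl$merge_history$height) >= -1e-12))
  expect_identical(cluster_accessions(z, 3)$clusters, cl$clusters)
})

test_that("well-separated groups are recovered exactly", {
  skip_if_not_installed("mclust")
  set.seed(8)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), nrow = 3, byrow = TRUE)
  lab <- rep(1:3, each = 5)
  x <- centers[lab, c(1, 2, 1, 2)] + matrix(rnorm(15 * 4, sd = 0.5), 15, 4)
  dimnames(x) <- list(sprintf("A%02d", 1:15), paste0("t", 1:4))
  cl <- cluster_accessions(standardize_blup(x), 3)
  expect_equal(adjusted_rand_index(cl$clusters, lab), 1)
  # our ARI implementation agrees with mclust's
  expect_equal(adjusted_rand_index(cl$clusters, lab),
               mclust::adjustedRandIndex(cl$clusters, lab))
  set.seed(31)
  pa <- sample(1:4, 60, TRUE); pb <- sample(1:3, 60, TRUE)
  expect_equal(adjusted_rand_index(pa, pb), mclust::adjustedRandIndex(pa, pb))
})

test_that("group means are exact averages in original units", {
  bm <- build_blup_matrix(demo_seed_dataset(seed = 2), "across_years")
  # k = 1: column means
  g1 <- group_means(bm, setNames(rep(1L, 15), bm$accessions))
  expect_equal(unname(g1$means[1L, ]), unname(colMeans(bm$values)))
  # singletons: the accession rows themselves
  gn <- group_means(bm, setNames(seq_len(15), bm$accessions))
  expect_equal(unname(gn$means), unname(bm$values))
  # constructed two-group offsets are recovered exactly
  m <- rbind(matrix(1, 4, 3), matrix(5, 2, 3))
  dimnames(m) <- list(paste0("a", 1:6), paste0("t", 1:3))
  gm <- group_means(m, setNames(rep(1:2, c(4, 2)), rownames(m)))
  expect_equal(unname(gm$means), rbind(rep(1, 3), rep(5, 3)))
  expect_equal(unname(gm$sizes), c(4L, 2L))
  expect_error(group_means(bm, setNames(rep(1L, 15), paste0("X", 1:15))),
               "unknown accession")
})

test_that("pattern_analysis bundles consistent pieces", {
  bm <- build_blup_matrix(demo_seed_dataset(seed = 22), "across_years")
  pat <- pattern_analysis(bm, k = 3)
  expect_s3_class(pat, "pattern_result")
  expect_equal(sum(pat$pct_var), 100, tolerance = 1e-9)
  expect_equal(sort(unique(unname(pat$clusters))), 1:3)
  expect_equal(sum(pat$group_sizes), 15L)
  # group ids follow first appearance in accession order
  expect_equal(unname(pat$clusters[1L]), 1L)
  z <- standardize_blup(bm)
  expect_equal(pat$scores, pca_biplot(z)$scores)
  expect_equal(pat$group_means,
               group_means(bm, pat$clusters)$means)
})
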