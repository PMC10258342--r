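test_that("Pearson correlations and t-test p-values match hand computation", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(2, 4, 6, 8),
             d = c(4, 3, 2, 1))
  cm <- phenotypic_correlation(m)
  expect_equal(cm$r["a", "c"], 1)        # proportional columns
  expect_equal(cm$r["a", "d"], -1)       # reversed order
  expect_equal(cm$r["a", "b"], 0.8)
  tstat <- 0.8 * sqrt(2 / 0.36)
  expect_equal(cm$p["a", "b"], 2 * pt(tstat, 2, lower.tail = FALSE))
  expect_equal(cm$p["a", "c"], 0)
  expect_equal(cm$n, 4L)
})

test_that("correlation matrices are symmetric, unit-diagonal and PSD", {
  bm <- build_blup_matrix(demo_seed_dataset(seed = 9), "across_years")
  cm <- phenotypic_correlation(bm)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 9))
  expect_true(all(abs(cm$r) <= 1))
  expect_gte(min(eigen(cm$r, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # stars agree with p at the thresholds everywhere
  off <- !is.na(cm$p)
  expect_identical(cm$stars[off],
                   ifelse(cm$p[off] < 0.01, "**",
                          ifelse(cm$p[off] < 0.05, "*", "")))
})

test_that("correlation preconditions are enforced", {
  expect_error(phenotypic_correlation(cbind(a = c(1, 1, 1), b = c(1, 2, 3))),
               "constant column\\(s\\): a")
  expect_error(phenotypic_correlation(cbind(a = 1:2, b = 2:1)),
               ">= 3 observations")
})

test_that("star assignment is a pure threshold function of p", {
  p <- c(0.0001, 0.00999, 0.01, 0.049, 0.05, 0.2, NA)
  expect_identical(seedvar:::.stars(p), c("**", "**", "*", "*", "", "", ""))
})

test_that("SSCP strata are additive and consistent with univariate ANOVA", {
  ds <- demo_seed_dataset(seed = 4)
  s <- sscp_strata(ds, year = 2014)
  expect_equal(s$between, t(s$between))
  expect_equal(s$within, t(s$within))
  # total SSCP of grand-mean-adjusted data equals between + within
  r <- ds$records[ds$records$year == 2014, ]
  key <- paste(r$accession, r$replicate, sep = "\r")
  wide <- sapply(ds$traits, function(t) {
    v <- r[r$trait == t, ]
    v$value[order(paste(v$accession, v$replicate, sep = "\r"))]
  })
  total <- crossprod(scale(wide, scale = FALSE))
  expect_equal(unname(s$between + s$within), unname(total), tolerance = 1e-8)
  # diagonal of between / df equals the genotype mean square
  vc <- fit_single_year(ds, "perimeter", 2014)
  expect_equal(s$between["perimeter", "perimeter"] / s$df_between, vc$ms_g)
  expect_equal(s$df_between, 14L)
  expect_equal(s$df_within, 30L)
})

test_that("across-years SSCP adjusts for year fixed effects", {
  ds <- demo_seed_dataset(seed = 4)
  s <- sscp_strata(ds)
  expect_equal(s$df_between, 14L)
  expect_equal(s$df_within, 90L - 15L - 2L + 1L)
  # zero-noise additive data: the within stratum vanishes
  s0 <- sscp_strata(toy_additive_across())
  expect_equal(unname(s0$within), matrix(0, 1, 1), tolerance = 1e-20)
  expect_gt(s0$between[1, 1], 0)
})

test_that("SSCP rejects traits with unequal record coverage", {
  ds <- demo_seed_dataset(seed = 4)
  r <- ds$records
  drop <- which(r$trait == "perimeter")[1L]
  expect_error(sscp_strata(trait_dataset(r[-drop, ])),
               "unequal record coverage.*perimeter")
})

test_that("trait-environment correlations follow the same conventions", {
  bm <- build_blup_matrix(demo_seed_dataset(seed = 13), "across_years")
  meta <- data.frame(accession = bm$accessions,
                     altitude = as.numeric(bm$values[, "perimeter"]),
                     noise = NA_real_)
  set.seed(1)
  meta$noise <- rnorm(15)
  ec <- env_correlation(bm, meta)
  expect_equal(ec$r["perimeter", "altitude"], 1)
  expect_false(ec$square)
  expect_equal(dim(ec$r), c(9L, 2L))

  expect_error(env_correlation(bm, meta[-1L, ]), "missing from site metadata")
  meta$flat <- 1
  expect_error(env_correlation(bm, meta, covariates = "flat"),
               "constant column")
  expect_error(env_correlation(bm, meta, covariates = "nope"),
               "not in metadata")
})

test_that("a permuted covariate shows no systematic association", {
  bm <- build_blup_matrix(demo_seed_dataset(seed = 13), "across_years")
  set.seed(99)
  ps <- replicate(40, {
    meta <- data.frame(accession = bm$accessions,
                       alt = sample(as.numeric(bm$values[, "perimeter"])))
    env_correlation(bm, meta)$p["seed_length", "alt"]
  })
  expect_gt(mean(ps), 0.25)  # p-values roughly uniform under the null
  expect_lt(mean(abs(ps - 0.5)), 0.45)
})

test_that("components-based correlations are consistent with univariate EMS", {
  ds <- demo_seed_dataset(seed = 9)
  cm <- phenotypic_correlation_components(ds, year = 2014)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 9))
  expect_true(all(abs(cm$r) <= 1))
  expect_true(all(cm$stars == ""))
  # a trait pair that is a near-deterministic function of itself correlates 1
  r <- ds$records[ds$records$trait == "perimeter", ]
  r2 <- r; r2$trait <- "peri2"; r2$value <- 2 * r2$value + 1
  ds2 <- trait_dataset(rbind(ds$records, r2))
  cm2 <- phenotypic_correlation_components(ds2, c("perimeter", "peri2"), 2014)
  expect_equal(cm2$r["perimeter", "peri2"], 1, tolerance = 1e-12)
  expect_error(phenotypic_correlation_components(ds, "perimeter", 2014),
               ">= 2 traits")
})
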