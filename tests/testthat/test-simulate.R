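test_that("one seed yields one dataset, bit for bit", {
  cfg <- demo_trial_config(seed = 77)
  d1 <- simulate_dataset(cfg$config, cfg$gc)
  d2 <- simulate_dataset(cfg$config, cfg$gc)
  expect_identical(d1$records, d2$records)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_trait_table(d1, p1); write_trait_table(d2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  cfg$config$seed <- 78L
  expect_false(identical(simulate_dataset(cfg$config, cfg$gc)$records$value,
                         d1$records$value))
})

test_that("degenerate noise collapses every value to the trait mean", {
  cfg <- sim_config(list(trait_spec("a", 3.5, 0, 0, 0),
                         trait_spec("b", 0.8, 0, 0, 0)),
                    n_accessions = 4, years = c(2014L, 2019L), nr = 2,
                    seed = 5)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$records$value[ds$records$trait == "a"] == 3.5))
  expect_true(all(ds$records$value[ds$records$trait == "b"] == 0.8))
})

test_that("empirical moments match the generating components at scale", {
  cfg <- sim_config(list(trait_spec("t", 10, 0.2, 0.05, 0.1)),
                    n_accessions = 200, years = c(2014L, 2019L), nr = 3,
                    seed = 123)
  ds <- simulate_dataset(cfg)
  r <- ds$records
  # within-cell variance estimates sigma_e2
  vc <- fit_across_years(ds, "t")
  expect_equal(vc$sigma_e2, 0.1, tolerance = 0.15)
  expect_equal(vc$sigma_gy2, 0.05, tolerance = 0.3)
  expect_equal(vc$sigma_g2, 0.2, tolerance = 0.15)
  # law of total variance for the accession-mean deviations:
  # var = sigma_g2 + sigma_gy2/nl + sigma_e2/(nl nr)
  m_i <- tapply(r$value, r$accession, mean)
  expect_equal(var(as.numeric(m_i)), 0.2 + 0.05 / 2 + 0.1 / 6,
               tolerance = 0.15)
})

test_that("cross-trait genetic correlations are reproduced", {
  traits <- c("x", "y", "z")
  rho <- matrix(c(1, 0.7, 0.3, 0.7, 1, 0, 0.3, 0, 1), 3, 3)
  gc <- genetic_correlation(traits, rho)
  cfg <- sim_config(list(trait_spec("x", 0, 1, 0, 0.01),
                         trait_spec("y", 0, 1, 0, 0.01),
                         trait_spec("z", 0, 1, 0, 0.01)),
                    n_accessions = 5000, years = 2014L, nr = 2, seed = 9)
  ds <- simulate_dataset(cfg, gc)
  g <- attr(ds, "true_effects")
  expect_lt(max(abs(cor(g) - rho)), 0.05)
})

test_that("generator inputs are validated", {
  traits <- c("x", "y")
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(genetic_correlation(traits, bad), "positive semi-definite")
  expect_error(genetic_correlation(traits, diag(3)), "must be 2 x 2")
  rho <- genetic_correlation(c("a", "b"), diag(2))
  cfg <- sim_config(list(trait_spec("x", 0, 1, 0, 1)), seed = 1)
  expect_error(simulate_dataset(cfg, rho), "do not match")
  expect_error(trait_spec("t", 1, -0.1, 0, 1), "non-negative")
  expect_error(trait_spec("t", 1, 0.1, 0, 1, year_effects = c(1, 1)),
               "sum to zero")
})

test_that("recovery experiments aggregate fits against the truth", {
  cfg <- sim_config(list(trait_spec("t", 10, 0.2, 0.05, 0.1,
                                    year_effects = c(-0.3, 0.3))),
                    n_accessions = 15, years = c(2014L, 2019L), nr = 3,
                    seed = 1)
  rep1 <- recovery_experiment(cfg, n_sims = 1, seed = 50)
  expect_equal(rep1$n_sims, 1L)
  expect_equal(dim(rep1$estimates), c(1L, 1L, 4L))
  expect_equal(rep1$summary$true_R2,
               repeatability_across(0.2, 0.05, 0.1, 2, 3)$value)

  # under a null genotype, clamping piles estimates up at exactly zero
  cfg0 <- sim_config(list(trait_spec("t", 10, 0, 0.05, 0.1)),
                     n_accessions = 10, years = c(2014L, 2019L), nr = 3,
                     seed = 1)
  rep0 <- recovery_experiment(cfg0, n_sims = 60, seed = 7)
  expect_gt(mean(rep0$estimates[, 1, "sigma_g2"] == 0), 0.25)
  expect_lt(rep0$summary$mean_sigma_g2, 0.05)
})

test_that("the demo trial has the declared design and plausible means", {
  ds <- demo_seed_dataset(seed = 11)
  d <- validate_design(ds)
  expect_equal(d$n_accessions, 15L)
  expect_equal(d$nl, 2L)
  expect_equal(d$nr, 3L)
  expect_true(d$balanced)
  expect_equal(length(ds$traits), 9L)

  cfg <- demo_trial_config(seed = 11)$config
  for (tr in ds$traits) {
    ts <- cfg$traits[[tr]]
    nl <- 2; nr <- 3; a <- 15
    se <- sqrt(ts$sigma_g2 / a + ts$sigma_gy2 / (a * nl) +
                 ts$sigma_e2 / (a * nl * nr))
    got <- mean(ds$records$value[ds$records$trait == tr])
    expect_lt(abs(got - ts$mu), 3 * se + 1e-12)
  }
  # the demo genetic correlation is a valid PSD correlation matrix
  gc <- demo_trial_config(seed = 11)$gc
  expect_gte(min(eigen(gc$rho, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_equal(unname(diag(gc$rho)), rep(1, 9))
})

test_that("record deletion produces the requested unbalance", {
  ds <- demo_seed_dataset(seed = 1)
  ds2 <- drop_records(ds, 0.1, seed = 2)
  expect_equal(nrow(ds2$records), nrow(ds$records) - 81L)
  expect_false(validate_design(ds2)$balanced)
  expect_identical(drop_records(ds, 0), ds)
})
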