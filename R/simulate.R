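# Synthetic trial generator.  Draws datasets from exactly the statistical
# structure the estimators assume:
#   y_ijkt = mu_t + Y_jt + g_it + (gY)_ijt + e_ijkt
# with fixed year offsets Y_jt, accession effects g_t drawn jointly across
# traits from a zero-mean multivariate normal with covariance
# diag(s_g) rho diag(s_g), and independent normal interaction and residual
# draws.  One seed, one dataset, bit for bit.

#' Specify one simulated trait
#'
#' @param name trait name.
#' @param mu grand mean in trait units.
#' @param sigma_g2 genotypic variance.
#' @param sigma_gy2 genotype-by-year interaction variance.
#' @param sigma_e2 residual variance.
#' @param year_effects optional numeric vector of per-year fixed offsets
#'   (recycled/validated against the config's years; must sum to zero).
#'   Defaults to all-zero.
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(name, mu, sigma_g2, sigma_gy2 = 0, sigma_e2,
                       year_effects = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  .check_vc_inputs(sigma_g2, sigma_gy2, sigma_e2)
  if (!is.null(year_effects)) {
    if (abs(sum(year_effects)) > 1e-8 * max(1, max(abs(year_effects)))) {
      .stopf("year_effects of trait '%s' must sum to zero", name)
    }
  }
  structure(list(name = name, mu = mu, sigma_g2 = sigma_g2,
                 sigma_gy2 = sigma_gy2, sigma_e2 = sigma_e2,
                 year_effects = year_effects),
            class = "trait_spec")
}

#' Simulation configuration
#'
#' Defaults mirror a two-year germplasm seed trial: 15 accessions, years
#' 2014 and 2019, three replicates per accession and year.
#'
#' @param traits list of [trait_spec()] objects with unique names.
#' @param n_accessions number of accessions.
#' @param years vector of calendar years.
#' @param nr replicates per (accession, year) cell.
#' @param seed integer random seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(traits, n_accessions = 15, years = c(2014, 2019),
                       nr = 3, seed = 1) {
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  stopifnot(length(traits) >= 1L,
            all(vapply(traits, inherits, logical(1L), "trait_spec")))
  nms <- vapply(traits, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) .stopf("duplicate trait names in config")
  if (!.is_count(n_accessions) || !.is_count(nr)) {
    .stopf("`n_accessions` and `nr` must be positive integers")
  }
  for (ts in traits) {
    if (!is.null(ts$year_effects) && length(ts$year_effects) != length(years)) {
      .stopf("trait '%s' has %d year effects for %d years",
             ts$name, length(ts$year_effects), length(years))
    }
  }
  structure(list(n_accessions = as.integer(n_accessions),
                 years = as.integer(years), nr = as.integer(nr),
                 traits = stats::setNames(traits, nms), seed = as.integer(seed)),
            class = "sim_config")
}

#' Cross-trait genetic correlation structure
#'
#' A symmetric positive semi-definite correlation matrix applied to the
#' accession (genotypic) effects across traits; interaction and residual
#' draws stay trait-independent.
#'
#' @param traits ordered trait names.
#' @param rho correlation matrix (unit diagonal, PSD within `-1e-10`).
#' @return A list of class `genetic_correlation`.
#' @export
genetic_correlation <- function(traits, rho) {
  rho <- as.matrix(rho)
  k <- length(traits)
  if (!all(dim(rho) == k)) .stopf("rho must be %d x %d", k, k)
  if (max(abs(rho - t(rho))) > 1e-10) .stopf("rho must be symmetric")
  if (max(abs(diag(rho) - 1)) > 1e-10) .stopf("rho must have unit diagonal")
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    .stopf("rho is not positive semi-definite (min eigenvalue %.3g)", min(ev))
  }
  dimnames(rho) <- list(traits, traits)
  structure(list(traits = traits, rho = rho), class = "genetic_correlation")
}

# matrix square root of a PSD correlation matrix (eigen route tolerates
# semidefiniteness; deterministic)
.psd_sqrt <- function(rho) {
  eg <- eigen(rho, symmetric = TRUE)
  eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
}

#' Simulate a balanced trial dataset
#'
#' Draws a [trait_dataset()] from the generative mirror of the analysis
#' model.  All randomness derives from `cfg$seed`; draws follow a fixed
#' order (accession effects for all traits jointly, then per trait the
#' interaction effects, then the residuals), so the same seed always yields
#' a byte-identical dataset.  Accessions are labelled `"A01"`, `"A02"`, ...
#'
#' @param cfg a [sim_config()].
#' @param gc optional [genetic_correlation()] covering the config's traits
#'   in order; omitted, accession effects are independent across traits.
#' @return A balanced [trait_dataset()].
#' @export
simulate_dataset <- function(cfg, gc = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  nms <- names(cfg$traits)
  Tn <- length(nms)
  if (!is.null(gc)) {
    stopifnot(inherits(gc, "genetic_correlation"))
    if (!identical(gc$traits, nms)) {
      .stopf("genetic correlation traits do not match config traits")
    }
  }
  a <- cfg$n_accessions
  nl <- length(cfg$years)
  nr <- cfg$nr
  acc <- sprintf("A%02d", seq_len(a))
  set.seed(cfg$seed)
  sd_g <- sqrt(vapply(cfg$traits, `[[`, numeric(1L), "sigma_g2"))
  gmat <- matrix(stats::rnorm(a * Tn), nrow = a, ncol = Tn)
  if (!is.null(gc)) gmat <- gmat %*% .psd_sqrt(gc$rho)
  gmat <- sweep(gmat, 2L, sd_g, `*`)        # accession effects, a x T
  colnames(gmat) <- nms

  res <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    ts <- cfg$traits[[t]]
    ye <- ts$year_effects %||% rep(0, nl)
    gy <- matrix(stats::rnorm(a * nl, sd = sqrt(ts$sigma_gy2)), a, nl)
    eps <- array(stats::rnorm(a * nl * nr, sd = sqrt(ts$sigma_e2)),
                 dim = c(a, nl, nr))
    val <- array(NA_real_, dim = c(a, nl, nr))
    for (j in seq_len(nl)) {
      val[, j, ] <- ts$mu + ye[j] + gmat[, t] + gy[, j] + eps[, j, ]
    }
    res[[t]] <- val
  }
  # assemble records: accession outermost, then year, replicate, trait
  grid <- expand.grid(trait = seq_len(Tn), replicate = seq_len(nr),
                      year = seq_len(nl), accession = seq_len(a),
                      KEEP.OUT.ATTRS = FALSE)
  values <- mapply(function(t, k, j, i) res[[t]][i, j, k],
                   grid$trait, grid$replicate, grid$year, grid$accession)
  ds <- trait_dataset(data.frame(
    accession = acc[grid$accession],
    year = cfg$years[grid$year],
    replicate = grid$replicate,
    trait = nms[grid$trait],
    value = values,
    stringsAsFactors = FALSE))
  attr(ds, "true_effects") <- gmat
  ds
}

#' Randomly delete records to create an unbalanced dataset
#'
#' @param ds a [trait_dataset()].
#' @param frac fraction of records to drop, in `[0, 1)`.
#' @param seed integer seed for the deletion draw.
#' @return A [trait_dataset()] with `floor(frac * n)` records removed.
#' @export
drop_records <- function(ds, frac, seed = 1) {
  stopifnot(inherits(ds, "trait_dataset"), frac >= 0, frac < 1)
  n <- nrow(ds$records)
  k <- floor(frac * n)
  if (k == 0L) return(ds)
  set.seed(seed)
  keep <- setdiff(seq_len(n), sample.int(n, k))
  trait_dataset(ds$records[keep, , drop = FALSE])
}

#' Parameter-recovery experiment
#'
#' Simulates `n_sims` datasets from `cfg` (per-simulation seeds
#' `seed + 1, ..., seed + n_sims`), fits the across-years model to every
#' trait with [fit_across_years()], and aggregates the estimates against the
#' generating truth, including the across-years repeatability R2.
#' Per-simulation fit failures are recorded; more than 10 percent of
#' failures is an error.
#'
#' @param cfg a [sim_config()] (its own `seed` field is ignored here).
#' @param n_sims number of simulated datasets.
#' @param seed integer base seed.
#' @param gc optional [genetic_correlation()] passed to the simulator.
#' @return An object of class `recovery_report`: a list with `n_sims`,
#'   `n_failed`, and `summary`, a data.frame with one row per trait holding
#'   the true components, the mean and sd of each estimate, the mean
#'   estimated R2, the true R2, and the biases.
#' @export
recovery_experiment <- function(cfg, n_sims, seed = 1, gc = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!.is_count(n_sims)) .stopf("`n_sims` must be a positive integer")
  nms <- names(cfg$traits)
  nl <- length(cfg$years)
  nr <- cfg$nr
  est <- array(NA_real_, dim = c(n_sims, length(nms), 4L),
               dimnames = list(NULL, nms,
                               c("sigma_g2", "sigma_gy2", "sigma_e2", "R2")))
  n_failed <- 0L
  for (s in seq_len(n_sims)) {
    cfg_s <- cfg
    cfg_s$seed <- as.integer(seed + s)
    ds <- simulate_dataset(cfg_s, gc)
    for (t in nms) {
      vc <- tryCatch(fit_across_years(ds, t), error = function(e) NULL)
      if (is.null(vc)) { n_failed <- n_failed + 1L; next }
      r2 <- tryCatch(repeatability(vc)$value, error = function(e) NA_real_)
      est[s, t, ] <- c(vc$sigma_g2, vc$sigma_gy2, vc$sigma_e2, r2)
    }
  }
  if (n_failed > 0.1 * n_sims * length(nms)) {
    .stopf("%d of %d per-trait fits failed", n_failed, n_sims * length(nms))
  }
  rows <- lapply(nms, function(t) {
    ts <- cfg$traits[[t]]
    true_r2 <- repeatability_across(ts$sigma_g2, ts$sigma_gy2, ts$sigma_e2,
                                    nl, nr)$value
    data.frame(
      trait = t,
      true_sigma_g2 = ts$sigma_g2, true_sigma_gy2 = ts$sigma_gy2,
      true_sigma_e2 = ts$sigma_e2, true_R2 = true_r2,
      mean_sigma_g2 = mean(est[, t, "sigma_g2"], na.rm = TRUE),
      sd_sigma_g2 = stats::sd(est[, t, "sigma_g2"], na.rm = TRUE),
      mean_sigma_gy2 = mean(est[, t, "sigma_gy2"], na.rm = TRUE),
      sd_sigma_gy2 = stats::sd(est[, t, "sigma_gy2"], na.rm = TRUE),
      mean_sigma_e2 = mean(est[, t, "sigma_e2"], na.rm = TRUE),
      sd_sigma_e2 = stats::sd(est[, t, "sigma_e2"], na.rm = TRUE),
      mean_R2 = mean(est[, t, "R2"], na.rm = TRUE),
      sd_R2 = stats::sd(est[, t, "R2"], na.rm = TRUE),
      bias_sigma_g2 = mean(est[, t, "sigma_g2"], na.rm = TRUE) - ts$sigma_g2,
      bias_R2 = mean(est[, t, "R2"], na.rm = TRUE) - true_r2,
      stringsAsFactors = FALSE)
  })
  structure(list(n_sims = as.integer(n_sims), n_failed = n_failed,
                 estimates = est, summary = do.call(rbind, rows)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d simulations (%d fit failures)\n",
              x$n_sims, x$n_failed))
  print(x$summary[, c("trait", "true_sigma_g2", "mean_sigma_g2",
                      "bias_sigma_g2", "true_R2", "mean_R2", "bias_R2")],
        digits = 4, row.names = FALSE)
  invisible(x)
}

# reference configuration for a two-year, nine-trait seed-morphology trial
# of a high-altitude leguminous shrub: 15 accessions x 2 years x 3 scanned
# replicates of 100 seeds.  Means, variance components and year offsets are
# set to magnitudes typical of such a trial (perimeter/length/width/
# thickness in mm, hilum dimensions in mm, two dimensionless shape ratios,
# 100-seed weight in g).
.demo_trait_table <- function() {
  tab <- data.frame(
    name = c("perimeter", "seed_length", "seed_width", "width_length",
             "hilum_length", "hilum_width", "hilum_wl", "seed_thickness",
             "seed_weight_100"),
    mu = c(14.778, 4.522, 4.470, 0.989, 1.782, 1.297, 0.729, 3.652, 0.830),
    mean_y1 = c(14.661, 4.453, 4.405, 0.990, 1.790, 1.295, 0.725, 3.594, 0.791),
    mean_y2 = c(14.959, 4.592, 4.554, 0.992, 1.773, 1.307, 0.738, 3.730, 0.876),
    sigma_g2 = c(0.055, 0.043, 0.072, 0.068, 0.180, 0.260, 0.016, 0.058, 0.099),
    sigma_gy2 = c(0.005, 0.005, 0.008, 0.046, 0.052, 0.069, 0.003, 0.004, 0.015),
    sigma_e2 = c(0.154, 0.016, 0.111, 0.042, 0.080, 0.450, 0.382, 0.004, 0.003),
    stringsAsFactors = FALSE)
  tab
}

# qualitative cross-trait genetic correlation pattern for the demo traits:
# the size/weight complex (perimeter, length, width, thickness, 100-seed
# weight) strongly positive, hilum shape ratio negatively related to it.
# Projected to the nearest PSD correlation matrix (eigenvalue clamping,
# rescaled to unit diagonal) so it is a valid generator input.
.demo_rho <- function(traits) {
  k <- length(traits)
  rho <- diag(k)
  dimnames(rho) <- list(traits, traits)
  set_r <- function(i, j, v) {
    rho[i, j] <<- v
    rho[j, i] <<- v
  }
  set_r("perimeter", "seed_length", 0.95)
  set_r("perimeter", "seed_width", 0.91)
  set_r("perimeter", "seed_thickness", 0.60)
  set_r("perimeter", "seed_weight_100", 0.56)
  set_r("perimeter", "hilum_length", 0.47)
  set_r("perimeter", "hilum_wl", -0.44)
  set_r("seed_length", "seed_width", 0.83)
  set_r("seed_length", "seed_thickness", 0.58)
  set_r("seed_length", "seed_weight_100", 0.57)
  set_r("seed_length", "hilum_length", 0.43)
  set_r("seed_length", "hilum_wl", -0.44)
  set_r("seed_length", "width_length", -0.29)
  set_r("seed_width", "width_length", 0.29)
  set_r("seed_width", "seed_thickness", 0.76)
  set_r("seed_width", "seed_weight_100", 0.72)
  set_r("seed_width", "hilum_length", 0.47)
  set_r("seed_width", "hilum_wl", -0.58)
  set_r("seed_width", "hilum_width", -0.22)
  set_r("width_length", "seed_thickness", 0.30)
  set_r("width_length", "seed_weight_100", 0.27)
  set_r("width_length", "hilum_width", -0.24)
  set_r("width_length", "hilum_wl", -0.26)
  set_r("hilum_length", "hilum_width", 0.30)
  set_r("hilum_length", "hilum_wl", -0.61)
  set_r("hilum_length", "seed_thickness", 0.31)
  set_r("hilum_length", "seed_weight_100", 0.45)
  set_r("hilum_width", "hilum_wl", 0.57)
  set_r("hilum_width", "seed_thickness", -0.55)
  set_r("hilum_width", "seed_weight_100", -0.52)
  set_r("hilum_wl", "seed_thickness", -0.74)
  set_r("hilum_wl", "seed_weight_100", -0.83)
  set_r("seed_thickness", "seed_weight_100", 0.86)
  # nearest-PSD adjustment: clamp eigenvalues, restore unit diagonal
  eg <- eigen(rho, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-4)
  adj <- eg$vectors %*% (vals * t(eg$vectors))
  d <- sqrt(diag(adj))
  adj <- adj / tcrossprod(d)
  adj <- (adj + t(adj)) / 2
  diag(adj) <- 1
  dimnames(adj) <- list(traits, traits)
  adj
}

#' Reference configuration of the demo seed trial
#'
#' The configuration behind [demo_seed_dataset()]: nine seed-morphology
#' traits with realistic means, year offsets and variance components for a
#' 15-accession, two-year, three-replicate trial, plus a cross-trait genetic
#' correlation matrix with a strongly positively correlated size/weight
#' complex.
#'
#' @param seed integer seed stored in the config.
#' @return A list with elements `config` ([sim_config()]) and `gc`
#'   ([genetic_correlation()]).
#' @export
demo_trial_config <- function(seed = 1) {
  tab <- .demo_trait_table()
  traits <- lapply(seq_len(nrow(tab)), function(i) {
    half <- (tab$mean_y2[i] - tab$mean_y1[i]) / 2
    trait_spec(tab$name[i], mu = tab$mu[i],
               sigma_g2 = tab$sigma_g2[i], sigma_gy2 = tab$sigma_gy2[i],
               sigma_e2 = tab$sigma_e2[i], year_effects = c(-half, half))
  })
  cfg <- sim_config(traits, n_accessions = 15, years = c(2014L, 2019L),
                    nr = 3, seed = seed)
  gc <- genetic_correlation(tab$name, .demo_rho(tab$name))
  list(config = cfg, gc = gc)
}

#' Synthetic demonstration dataset
#'
#' A balanced 15 accession x 2 year x 3 replicate x 9 trait dataset drawn
#' from [demo_trial_config()].  Entirely synthetic; used throughout the
#' examples and tests as a realistic stand-in for a two-year seed-trait
#' germplasm evaluation.
#'
#' @param seed integer random seed.
#' @return A [trait_dataset()].
#' @examples
#' ds <- demo_seed_dataset(seed = 42)
#' validate_design(ds)
#' @export
demo_seed_dataset <- function(seed = 1) {
  dt <- demo_trial_config(seed)
  simulate_dataset(dt$config, dt$gc)
}
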