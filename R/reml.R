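# Residual maximum likelihood.
#
# Two routes to the same estimator:
#  * em_reml(): an EM-type REML iteration on Henderson's mixed-model
#    equations, valid for balanced and unbalanced designs alike; monotone in
#    the restricted log-likelihood, estimates non-negative by construction.
#  * a closed-form constrained REML for balanced designs, used by
#    lrt_genotype(): on balanced data the restricted likelihood factorizes
#    over ANOVA strata, and the non-negativity constraints are solved by
#    pooling adjacent strata (pool-adjacent-violators on mean squares).

# ---- closed-form balanced REML over strata ---------------------------------

# Constrained maximizer of -1/2 * sum_s df_s (log l_s + ms_s / l_s)
# subject to l_1 >= l_2 >= ... >= l_S (variance expectations are nested).
# Weighted PAVA: pooled value of a block is sum(SS)/sum(df).
.pava_strata <- function(ss, df) {
  ms <- ss / df
  blocks <- lapply(seq_along(ms), function(i) list(ss = ss[i], df = df[i]))
  i <- 1L
  while (i < length(blocks)) {
    v1 <- blocks[[i]]$ss / blocks[[i]]$df
    v2 <- blocks[[i + 1L]]$ss / blocks[[i + 1L]]$df
    if (v1 < v2) {  # violates l_i >= l_{i+1}: pool
      blocks[[i]] <- list(ss = blocks[[i]]$ss + blocks[[i + 1L]]$ss,
                          df = blocks[[i]]$df + blocks[[i + 1L]]$df)
      blocks[[i + 1L]] <- NULL
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  lam <- numeric(length(ms))
  pos <- 1L
  for (b in blocks) {
    k <- 0L; acc <- 0L
    while (acc < b$df) { acc <- acc + df[pos + k]; k <- k + 1L }
    lam[pos:(pos + k - 1L)] <- b$ss / b$df
    pos <- pos + k
  }
  lam
}

# Restricted log-likelihood (up to a model-independent constant) of a
# balanced stratum decomposition at stratum variances lam.
.ll_strata <- function(ss, df, lam) {
  ok <- lam > 0
  if (any(ss[!ok] > 1e-300)) return(-Inf)
  -0.5 * sum(df[ok] * log(lam[ok]) + ss[ok] / lam[ok])
}

# Maximized restricted log-likelihoods of the full and the sigma_g2 = 0
# models on a balanced slice.  model: "single_year" or "across_years".
.balanced_lrt <- function(r, model) {
  if (model == "single_year") {
    an <- .anova_single(r)
    ss <- c(an$ss_g, an$ss_e)
    df <- c(an$df_g, an$df_e)
    lam_full <- .pava_strata(ss, df)
    # reduced model: sigma_g2 = 0 pools both strata into one
    lam0 <- rep(sum(ss) / sum(df), 2L)
    list(ll_full = .ll_strata(ss, df, lam_full),
         ll_reduced = .ll_strata(ss, df, lam0))
  } else {
    an <- .anova_across(r)
    ss <- c(an$ss_g, an$ss_gy, an$ss_e)
    df <- c(an$df_g, an$df_gy, an$df_e)
    lam_full <- .pava_strata(ss, df)
    # sigma_g2 = 0 forces the genotype and interaction strata to share one
    # expectation; the interaction >= residual constraint still applies
    lam_r <- .pava_strata(c(ss[1L] + ss[2L], ss[3L]), c(df[1L] + df[2L], df[3L]))
    lam0 <- c(lam_r[1L], lam_r[1L], lam_r[2L])
    list(ll_full = .ll_strata(ss, df, lam_full),
         ll_reduced = .ll_strata(ss, df, lam0))
  }
}

# ---- general EM-REML -------------------------------------------------------

# Design matrices for one trait slice.  Returns y, X (fixed), Zs (named list
# of random-effect indicator matrices).
.build_design <- function(r, model) {
  y <- r$value
  acc <- factor(r$accession, levels = unique(r$accession))
  if (model == "single_year") {
    X <- matrix(1, nrow = length(y), ncol = 1L)
    Zs <- list(genotype = stats::model.matrix(~ acc - 1))
  } else {
    yr <- factor(r$year, levels = sort(unique(r$year)))
    X <- stats::model.matrix(~ yr)
    gy <- interaction(acc, yr, drop = TRUE, lex.order = TRUE)
    Zs <- list(genotype = stats::model.matrix(~ acc - 1),
               genotype_year = stats::model.matrix(~ gy - 1))
  }
  list(y = y, X = X, Zs = Zs)
}

# Cholesky with a tiny progressive ridge for the nearly singular systems
# that arise when residual variance collapses toward zero.
.chol_safe <- function(M) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  jitter <- 1e-12 * mean(diag(M))
  while (is.null(ch) && jitter < mean(diag(M))) {
    ch <- tryCatch(chol(M + jitter * diag(nrow(M))), error = function(e) NULL)
    jitter <- jitter * 100
  }
  if (is.null(ch)) .stopf("mixed-model equations are numerically singular")
  ch
}

# Core EM-REML on y = X b + sum_k Z_k u_k + e, u_k ~ N(0, s2_k I).
# Classical formulation through the mixed-model equations: with
# M = W'W + diag(0, s2_e/s2_k I), T = M^-1, solution (b, u) = T W'y,
#   s2_k <- (u_k'u_k + s2_e tr(T_kk)) / q_k
#   s2_e <- y'(y - W sol) / (n - p)
# Components that collapse numerically to zero are pinned there (dropped
# from the model) and reported as truncated.
.em_reml_core <- function(y, X, Zs, init, sigma_e2_init, tol, max_iter) {
  n <- length(y)
  p <- qr(X)$rank
  K <- length(Zs)
  q <- vapply(Zs, ncol, integer(1L))
  active <- rep(TRUE, K)
  s2 <- init
  s2e <- sigma_e2_init
  # components below this share of the total variance are scientifically
  # zero; treating them so keeps the iteration away from singular systems
  pin_tol <- 1e-6 * max(stats::var(y), .Machine$double.eps)
  ll_trace <- numeric(0)
  trajectory <- matrix(NA_real_, nrow = 0L, ncol = K + 1L,
                       dimnames = list(NULL, c(names(Zs), "sigma_e2")))

  rebuild <- function() {
    Zact <- Zs[active]
    W <- do.call(cbind, c(list(X), unname(Zact)))
    idx <- vector("list", sum(active))
    pos <- ncol(X)
    for (i in seq_along(Zact)) {
      idx[[i]] <- pos + seq_len(ncol(Zact[[i]]))
      pos <- pos + ncol(Zact[[i]])
    }
    list(W = W, WtW = crossprod(W), Wty = crossprod(W, y), idx = idx)
  }
  dsn <- rebuild()

  # stable evaluation of the REML residual quadratic form
  # y'(y - W sol) = e'e + sol' D sol with D the shrinkage diagonal; the
  # naive yty - sol'W'y cancels catastrophically when noise is near zero
  resid_quad <- function(sol, ks) {
    e <- y - dsn$W %*% sol
    out <- sum(e * e)
    for (i in seq_along(ks)) {
      d <- dsn$idx[[i]]
      out <- out + (s2e / s2[ks[i]]) * sum(sol[d]^2)
    }
    out
  }

  loglik <- function() {
    ks <- which(active)
    M <- dsn$WtW
    for (i in seq_along(ks)) {
      d <- dsn$idx[[i]]
      M[cbind(d, d)] <- M[cbind(d, d)] + s2e / s2[ks[i]]
    }
    ch <- tryCatch(.chol_safe(M), error = function(e) NULL)
    if (is.null(ch)) return(NA_real_)
    sol <- backsolve(ch, forwardsolve(t(ch), dsn$Wty))
    equad <- resid_quad(sol, ks)
    qa <- sum(q[ks])
    -0.5 * ((n - p - qa) * log(s2e) + sum(q[ks] * log(s2[ks])) +
              2 * sum(log(diag(ch))) + equad / s2e)
  }

  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    ks <- which(active)
    M <- dsn$WtW
    for (i in seq_along(ks)) {
      d <- dsn$idx[[i]]
      M[cbind(d, d)] <- M[cbind(d, d)] + s2e / s2[ks[i]]
    }
    ch <- .chol_safe(M)
    Tmat <- chol2inv(ch)
    sol <- Tmat %*% dsn$Wty
    equad <- resid_quad(sol, ks)
    s2_new <- s2
    for (i in seq_along(ks)) {
      d <- dsn$idx[[i]]
      s2_new[ks[i]] <- (sum(sol[d]^2) + s2e * sum(diag(Tmat)[d])) / q[ks[i]]
    }
    s2e_new <- equad / (n - p)
    delta <- max(abs(c(s2_new - s2, s2e_new - s2e)))
    s2 <- s2_new
    s2e <- s2e_new
    trajectory <- rbind(trajectory, c(ifelse(active, s2, 0), s2e))
    # pin components that have collapsed to the boundary
    dead <- active & s2 < pin_tol
    if (any(dead)) {
      active[dead] <- FALSE
      s2[dead] <- 0
      dsn <- rebuild()
      if (!any(active)) { converged <- TRUE; ll_trace <- c(ll_trace, loglik()); break }
      next
    }
    ll_trace <- c(ll_trace, loglik())
    if (delta < tol) { converged <- TRUE; break }
    # degenerate perfect-fit data: residual variance at the boundary
    if (s2e < pin_tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    tail_traj <- utils::tail(trajectory, 5L)
    .stopf(paste0("EM-REML did not converge in %d iterations (last components: %s);",
                  " increase max_iter or tol"),
           max_iter, paste(sprintf("%.8g", tail_traj[nrow(tail_traj), ]),
                           collapse = ", "))
  }
  # final boundary clamp: components that converged within the pin band are
  # reported as exact zeros
  active[active & s2 < pin_tol] <- FALSE
  s2[!active] <- 0
  list(sigma2 = s2, sigma_e2 = s2e, truncated = names(Zs)[!active],
       iterations = iter, loglik = utils::tail(ll_trace, 1L),
       ll_trace = ll_trace, n = n, p = p)
}

# Large-sample SEs from the inverse expected information
# I_kl = 1/2 tr(P V_k P V_l) evaluated at the converged components.
.reml_se <- function(y, X, Zs, sigma2, sigma_e2) {
  n <- length(y)
  Vmats <- c(lapply(Zs, tcrossprod), list(residual = diag(n)))
  theta <- c(sigma2, sigma_e2)
  V <- Reduce(`+`, Map(`*`, Vmats, theta))
  Vi <- solve(V)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
  act <- which(theta > 0 | seq_along(theta) == length(theta))
  PV <- lapply(Vmats[act], function(Vk) P %*% Vk)
  m <- length(act)
  info <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    info[i, j] <- info[j, i] <- 0.5 * sum(PV[[i]] * t(PV[[j]]))
  }
  se <- rep(0, length(theta))
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(cov)) se[act] <- sqrt(pmax(diag(cov), 0))
  se
}

#' EM-type REML variance components
#'
#' Iterative residual maximum likelihood for the single-year or across-years
#' model, via the classical EM formulation on Henderson's mixed-model
#' equations.  Works on unbalanced data (missing cells, unequal replicate
#' counts); on balanced data with an interior solution it converges to the
#' expected-mean-squares estimates of [fit_single_year()] /
#' [fit_across_years()].  The restricted log-likelihood is non-decreasing
#' across iterations and all estimates are non-negative by construction;
#' components that collapse to the boundary are pinned at zero and flagged.
#'
#' Starting values are the method-of-moments solution when the design is
#' balanced, clamped below at `1e-6 * var(y)`; otherwise the total variance
#' is split equally across components.
#'
#' @param ds a [trait_dataset()].
#' @param trait trait name.
#' @param model `"single_year"` or `"across_years"`.
#' @param year required when `model = "single_year"` and the dataset spans
#'   several years.
#' @param tol convergence threshold on the largest absolute change of any
#'   component between successive iterations.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return A `varcomp_single` or `varcomp_across` object (see
#'   [fit_single_year()], [fit_across_years()]) with `method = "em_reml"` and
#'   attributes `iterations`, `loglik` (final restricted log-likelihood, up
#'   to a constant) and `ll_trace`.  Mean squares and their degrees of
#'   freedom are reported when the slice is balanced, `NA` otherwise.
#' @export
em_reml <- function(ds, trait, model = c("single_year", "across_years"),
                    year = NULL, tol = 1e-8, max_iter = 10000L) {
  model <- match.arg(model)
  if (model == "single_year" && is.null(year)) {
    yrs <- unique(.slice_trait(ds, trait)$year)
    if (length(yrs) > 1L) {
      .stopf("dataset spans %d years; pass `year` for the single-year model",
             length(yrs))
    }
    year <- yrs
  }
  r <- .slice_trait(ds, trait, if (model == "single_year") year else NULL)
  if (model == "across_years" && length(unique(r$year)) < 2L) {
    .stopf("single year of data; use model = \"single_year\"")
  }
  if (length(unique(r$accession)) < 2L) .stopf("need >= 2 accessions")
  counts <- table(r$accession, r$year)
  if (!any(counts >= 2L)) {
    .stopf("no cell has >= 2 replicates; residual variance not estimable")
  }
  d <- .build_design(r, model)
  vy <- stats::var(d$y)
  floor0 <- max(1e-6 * vy, .Machine$double.eps)
  # method-of-moments start where available
  init <- NULL
  an <- tryCatch(
    if (model == "single_year") {
      a <- .anova_single(r)
      list(s2 = c((a$ss_g / a$df_g - a$ss_e / a$df_e) / a$nr),
           se2 = a$ss_e / a$df_e)
    } else {
      a <- .anova_across(r)
      ms <- c(a$ss_g / a$df_g, a$ss_gy / a$df_gy, a$ss_e / a$df_e)
      list(s2 = c((ms[1] - ms[2]) / (a$nl * a$nr), (ms[2] - ms[3]) / a$nr),
           se2 = ms[3])
    }, error = function(e) NULL)
  K <- length(d$Zs)
  if (is.null(an)) {
    init <- list(s2 = rep(vy / (K + 1), K), se2 = vy / (K + 1))
  } else {
    init <- list(s2 = pmax(an$s2, floor0), se2 = max(an$se2, floor0))
  }
  fit <- .em_reml_core(d$y, d$X, d$Zs, init$s2, init$se2, tol, max_iter)
  se <- .reml_se(d$y, d$X, d$Zs, fit$sigma2, fit$sigma_e2)

  balanced_an <- tryCatch(
    if (model == "single_year") .anova_single(r) else .anova_across(r),
    error = function(e) NULL)
  a_n <- length(unique(r$accession))
  if (model == "single_year") {
    nr <- if (!is.null(balanced_an)) balanced_an$nr else NA_integer_
    out <- structure(
      list(trait = trait, year = as.integer(year),
           sigma_g2 = fit$sigma2[[1L]], sigma_e2 = fit$sigma_e2,
           se_g = se[1L], se_e = se[2L],
           ms_g = if (!is.null(balanced_an)) balanced_an$ss_g / balanced_an$df_g else NA_real_,
           ms_e = if (!is.null(balanced_an)) balanced_an$ss_e / balanced_an$df_e else NA_real_,
           df_g = if (!is.null(balanced_an)) balanced_an$df_g else NA_integer_,
           df_e = if (!is.null(balanced_an)) balanced_an$df_e else
             length(d$y) - length(unique(r$accession)),
           nr = nr, n_accessions = a_n, grand_mean = mean(r$value),
           truncated = "genotype" %in% fit$truncated, method = "em_reml"),
      class = c("varcomp_single", "varcomp"))
  } else {
    nl <- length(unique(r$year))
    trunc_map <- c(genotype = "sigma_g2", genotype_year = "sigma_gy2")
    out <- structure(
      list(trait = trait,
           sigma_g2 = fit$sigma2[[1L]], sigma_gy2 = fit$sigma2[[2L]],
           sigma_e2 = fit$sigma_e2,
           se_g = se[1L], se_gy = se[2L], se_e = se[3L],
           ms_g = if (!is.null(balanced_an)) balanced_an$ss_g / balanced_an$df_g else NA_real_,
           ms_gy = if (!is.null(balanced_an)) balanced_an$ss_gy / balanced_an$df_gy else NA_real_,
           ms_e = if (!is.null(balanced_an)) balanced_an$ss_e / balanced_an$df_e else NA_real_,
           df_g = if (!is.null(balanced_an)) balanced_an$df_g else NA_integer_,
           df_gy = if (!is.null(balanced_an)) balanced_an$df_gy else NA_integer_,
           df_e = if (!is.null(balanced_an)) balanced_an$df_e else
             length(d$y) - qr(cbind(d$X, d$Zs$genotype_year))$rank,
           nl = nl, nr = if (!is.null(balanced_an)) balanced_an$nr else NA_integer_,
           n_accessions = a_n, grand_mean = mean(r$value),
           year_means = tapply(r$value, r$year, mean),
           truncated_components = unname(trunc_map[fit$truncated]),
           method = "em_reml"),
      class = c("varcomp_across", "varcomp"))
  }
  attr(out, "iterations") <- fit$iterations
  attr(out, "loglik") <- fit$loglik
  attr(out, "ll_trace") <- fit$ll_trace
  attr(out, "converged") <- TRUE
  out
}

#' Likelihood-ratio test for genotypic variance
#'
#' Tests `H0: sigma_g2 = 0` against `H1: sigma_g2 > 0` by comparing the
#' restricted likelihoods of the full model and the model without the
#' genotype term (same fixed effects, so the REML contrast is valid).  The
#' null lies on the parameter boundary, so the reference distribution is the
#' mixture `0.5 chi2_0 + 0.5 chi2_1`: `p = 0.5 P(chi2_1 >= LR)` for `LR > 0`
#' and `p = 1` at `LR = 0`.
#'
#' Balanced slices use the exact stratum factorization of the restricted
#' likelihood (closed form); unbalanced slices fall back to two [em_reml()]
#' fits.
#'
#' @inheritParams em_reml
#' @return An object of class `genotypic_test` with fields `trait`,
#'   `lr_stat`, `p_value` and `model`.
#' @export
lrt_genotype <- function(ds, trait, model = c("single_year", "across_years"),
                         year = NULL) {
  model <- match.arg(model)
  if (model == "single_year" && is.null(year)) {
    yrs <- unique(.slice_trait(ds, trait)$year)
    if (length(yrs) > 1L) {
      .stopf("dataset spans %d years; pass `year` for the single-year model",
             length(yrs))
    }
    year <- yrs
  }
  r <- .slice_trait(ds, trait, if (model == "single_year") year else NULL)
  lls <- tryCatch(.balanced_lrt(r, model), error = function(e) NULL)
  if (is.null(lls)) {
    # unbalanced: dual EM fits with identical fixed effects
    full <- em_reml(ds, trait, model, year = year)
    d <- .build_design(r, model)
    Zs_red <- d$Zs[setdiff(names(d$Zs), "genotype")]
    vy <- stats::var(d$y)
    K <- length(Zs_red)
    red <- .em_reml_core(d$y, d$X, Zs_red,
                         rep(vy / (K + 1), max(K, 1L))[seq_len(K)],
                         vy / (K + 1), 1e-8, 10000L)
    # the MME log-likelihood and the attr on `full` share the same constant
    lls <- list(ll_full = attr(full, "loglik"), ll_reduced = red$loglik)
  }
  lr <- max(0, 2 * (lls$ll_full - lls$ll_reduced))
  if (lr < 1e-12) lr <- 0
  p <- if (lr == 0) 1 else 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  structure(list(trait = trait, lr_stat = lr, p_value = p, model = model),
            class = "genotypic_test")
}

#' @export
print.genotypic_test <- function(x, ...) {
  cat(sprintf("<genotypic_test> trait %s (%s): LR = %.4g, p = %.4g\n",
              x$trait, x$model, x$lr_stat, x$p_value))
  invisible(x)
}
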