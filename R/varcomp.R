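# Variance-component estimation on balanced designs via expected mean
# squares (the method-of-moments solution, which coincides with REML when the
# solution is interior), plus least significant differences.
#
# Single-year model:   y_ik  = mu + g_i + e_ik
# Across-years model:  y_ijk = mu + Y_j + g_i + (gY)_ij + e_ijk
# with g, (gY) and e independent zero-mean random effects and year Y_j fixed.

# ANOVA sums of squares for a balanced single-year slice.
# Returns list(ss_g, ss_e, df_g, df_e, nr, a, grand_mean, acc_means).
.anova_single <- function(r) {
  cell <- table(r$accession)
  a <- length(cell)
  if (a < 2L) .stopf("need >= 2 accessions, got %d", a)
  nr <- unique(as.integer(cell))
  if (length(nr) != 1L) {
    .stopf("unbalanced replicate counts per accession; use em_reml()")
  }
  if (nr < 2L) .stopf("need >= 2 replicates to estimate residual variance")
  acc_means <- tapply(r$value, r$accession, mean)
  grand <- mean(r$value)
  ss_g <- nr * sum((acc_means - grand)^2)
  ss_e <- sum((r$value - acc_means[r$accession])^2)
  list(ss_g = ss_g, ss_e = ss_e, df_g = a - 1L, df_e = a * (nr - 1L),
       nr = nr, a = a, grand_mean = grand, acc_means = acc_means)
}

# ANOVA sums of squares for a balanced two-way (accession x year) slice with
# nr replicates per cell.  Year enters as a fixed effect; its stratum is
# reported but never used for variance components.
.anova_across <- function(r) {
  acc <- unique(r$accession)
  yrs <- sort(unique(r$year))
  a <- length(acc)
  nl <- length(yrs)
  if (a < 2L) .stopf("need >= 2 accessions, got %d", a)
  if (nl < 2L) .stopf("single year of data; use fit_single_year()")
  cell <- table(r$accession, r$year)
  nr <- unique(as.integer(cell))
  if (length(nr) != 1L || nr == 0L) {
    .stopf("missing or unequal (accession, year) cells; use em_reml()")
  }
  if (nr < 2L) .stopf("need >= 2 replicates to estimate residual variance")
  grand <- mean(r$value)
  m_i <- tapply(r$value, r$accession, mean)
  m_j <- tapply(r$value, r$year, mean)
  m_ij <- tapply(r$value, list(r$accession, r$year), mean)
  ss_g <- nl * nr * sum((m_i - grand)^2)
  ss_y <- a * nr * sum((m_j - grand)^2)
  inter <- sweep(sweep(m_ij, 1L, m_i), 2L, m_j) + grand
  ss_gy <- nr * sum(inter^2)
  fit_cell <- m_ij[cbind(r$accession, as.character(r$year))]
  ss_e <- sum((r$value - fit_cell)^2)
  list(ss_g = ss_g, ss_gy = ss_gy, ss_e = ss_e, ss_y = ss_y,
       df_g = a - 1L, df_gy = (a - 1L) * (nl - 1L), df_e = a * nl * (nr - 1L),
       a = a, nl = nl, nr = nr, grand_mean = grand,
       acc_means = m_i, year_means = m_j)
}

#' Single-year variance components by expected mean squares
#'
#' Fits the one-way random-effects model `y_ik = mu + g_i + e_ik` to the
#' balanced records of one trait in one year and solves the expected mean
#' squares: `sigma_e2 = MS_e` and `sigma_g2 = (MS_g - MS_e)/nr`, the latter
#' clamped at zero (with `truncated = TRUE`) when the moment solution is
#' negative.  On balanced data with an interior solution these estimates
#' coincide with REML.  Standard errors use the large-sample mean-square
#' variance `Var(MS) = 2 MS^2 / df` propagated through the linear
#' combination.
#'
#' @param ds a [trait_dataset()].
#' @param trait trait name.
#' @param year calendar year to analyse.
#' @return An object of class `c("varcomp_single", "varcomp")` with fields
#'   `trait`, `year`, `sigma_g2`, `sigma_e2`, `se_g`, `se_e`, `ms_g`, `ms_e`,
#'   `df_g`, `df_e`, `nr`, `n_accessions`, `grand_mean`, `truncated`,
#'   `method`.
#' @seealso [em_reml()] for unbalanced data, [repeatability_single()],
#'   [lsd()]
#' @examples
#' ds <- trait_dataset(data.frame(
#'   accession = rep(c("A", "B", "C"), each = 2), year = 2014,
#'   replicate = rep(1:2, 3), trait = "SL",
#'   value = c(4, 6, 8, 10, 6, 8)))
#' fit_single_year(ds, "SL", 2014)  # sigma_g2 = 3, sigma_e2 = 2
#' @export
fit_single_year <- function(ds, trait, year) {
  r <- .slice_trait(ds, trait, year)
  if (nrow(r) == 0L) .stopf("no records for trait '%s' in year %s", trait, year)
  an <- .anova_single(r)
  ms_g <- an$ss_g / an$df_g
  ms_e <- an$ss_e / an$df_e
  sigma_g2 <- (ms_g - ms_e) / an$nr
  truncated <- sigma_g2 < 0
  if (truncated) sigma_g2 <- 0
  se_g <- sqrt(2 * ms_g^2 / an$df_g + 2 * ms_e^2 / an$df_e) / an$nr
  se_e <- ms_e * sqrt(2 / an$df_e)
  structure(
    list(trait = trait, year = as.integer(year),
         sigma_g2 = sigma_g2, sigma_e2 = ms_e,
         se_g = se_g, se_e = se_e,
         ms_g = ms_g, ms_e = ms_e, df_g = an$df_g, df_e = an$df_e,
         nr = an$nr, n_accessions = an$a, grand_mean = an$grand_mean,
         truncated = truncated, method = "ems"),
    class = c("varcomp_single", "varcomp"))
}

#' Across-years variance components by expected mean squares
#'
#' Fits the mixed model `y_ijk = mu + Y_j + g_i + (gY)_ij + e_ijk` (year
#' fixed; genotype and genotype-by-year random) to the balanced records of
#' one trait over all years and solves the expected mean squares:
#' `sigma_e2 = MS_e`, `sigma_gy2 = (MS_gy - MS_e)/nr`,
#' `sigma_g2 = (MS_g - MS_gy)/(nl nr)`, each clamped at zero independently
#' (clamped components are listed in `truncated_components`).
#'
#' @param ds a [trait_dataset()].
#' @param trait trait name.
#' @return An object of class `c("varcomp_across", "varcomp")` with the
#'   estimated components, standard errors, mean squares, degrees of freedom,
#'   design constants `nl`/`nr`, per-year fixed-effect means `year_means`, and
#'   `truncated_components`.
#' @seealso [em_reml()], [repeatability_across()], [lsd()]
#' @export
fit_across_years <- function(ds, trait) {
  r <- .slice_trait(ds, trait)
  an <- .anova_across(r)
  ms_g <- an$ss_g / an$df_g
  ms_gy <- an$ss_gy / an$df_gy
  ms_e <- an$ss_e / an$df_e
  sigma_e2 <- ms_e
  sigma_gy2 <- (ms_gy - ms_e) / an$nr
  sigma_g2 <- (ms_g - ms_gy) / (an$nl * an$nr)
  truncated <- character(0)
  if (sigma_gy2 < 0) { sigma_gy2 <- 0; truncated <- c(truncated, "sigma_gy2") }
  if (sigma_g2 < 0) { sigma_g2 <- 0; truncated <- c(truncated, "sigma_g2") }
  se_e <- ms_e * sqrt(2 / an$df_e)
  se_gy <- sqrt(2 * ms_gy^2 / an$df_gy + 2 * ms_e^2 / an$df_e) / an$nr
  se_g <- sqrt(2 * ms_g^2 / an$df_g + 2 * ms_gy^2 / an$df_gy) / (an$nl * an$nr)
  structure(
    list(trait = trait,
         sigma_g2 = sigma_g2, sigma_gy2 = sigma_gy2, sigma_e2 = sigma_e2,
         se_g = se_g, se_gy = se_gy, se_e = se_e,
         ms_g = ms_g, ms_gy = ms_gy, ms_e = ms_e,
         df_g = an$df_g, df_gy = an$df_gy, df_e = an$df_e,
         nl = an$nl, nr = an$nr, n_accessions = an$a,
         grand_mean = an$grand_mean,
         year_means = stats::setNames(as.numeric(an$year_means),
                                      names(an$year_means)),
         truncated_components = truncated, method = "ems"),
    class = c("varcomp_across", "varcomp"))
}

#' @export
print.varcomp <- function(x, ...) {
  if (inherits(x, "varcomp_single")) {
    cat(sprintf("<varcomp_single> trait %s, year %d [%s]\n", x$trait, x$year,
                x$method))
    cat(sprintf("  sigma_g2 = %.6g (SE %.3g)%s\n", x$sigma_g2, x$se_g,
                if (isTRUE(x$truncated)) " [clamped at 0]" else ""))
  } else {
    cat(sprintf("<varcomp_across> trait %s, %d years [%s]\n", x$trait, x$nl,
                x$method))
    cat(sprintf("  sigma_g2  = %.6g (SE %.3g)\n", x$sigma_g2, x$se_g))
    cat(sprintf("  sigma_gy2 = %.6g (SE %.3g)\n", x$sigma_gy2, x$se_gy))
    if (length(x$truncated_components)) {
      cat("  clamped at 0:", paste(x$truncated_components, collapse = ", "), "\n")
    }
  }
  cat(sprintf("  sigma_e2 = %.6g (SE %.3g)\n", x$sigma_e2, x$se_e))
  invisible(x)
}

#' Least significant difference between accession means
#'
#' `lsd = t(1 - alpha/2, df_e) * sqrt(2 * sigma_e2 / n_eff)`, the smallest
#' difference between two accession means declared significant at level
#' `alpha`.  By default each mean averages `nr` replicates within a year and
#' `nl * nr` across years.
#'
#' @param vc a fitted `varcomp_single` or `varcomp_across` object.
#' @param alpha significance level in (0, 1); default 0.05.
#' @param n_eff replication per accession mean; defaults to `nr` (single
#'   year) or `nl * nr` (across years).
#' @return An object of class `lsd_result` with fields `trait`, `alpha`,
#'   `lsd`, `df` and `n_eff`.
#' @export
lsd <- function(vc, alpha = 0.05, n_eff = NULL) {
  stopifnot(inherits(vc, "varcomp"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    .stopf("`alpha` must lie strictly between 0 and 1")
  }
  if (is.null(n_eff)) {
    n_eff <- if (inherits(vc, "varcomp_across")) vc$nl * vc$nr else vc$nr
  }
  if (!.is_count(n_eff)) .stopf("`n_eff` must be a positive integer")
  val <- stats::qt(1 - alpha / 2, df = vc$df_e) * sqrt(2 * vc$sigma_e2 / n_eff)
  structure(
    list(trait = vc$trait, alpha = alpha, lsd = val, df = vc$df_e,
         n_eff = n_eff),
    class = "lsd_result")
}

#' @export
print.lsd_result <- function(x, ...) {
  cat(sprintf("<lsd_result> trait %s: l.s.d._%g = %.6g (df = %d, n_eff = %d)\n",
              x$trait, x$alpha, x$lsd, x$df, x$n_eff))
  invisible(x)
}
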