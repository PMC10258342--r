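# Accession-mean repeatability and BLUP of accession means.
#
# Repeatability of accession means (the upper bound on broad-sense
# heritability of means):
#   within one year:  R1 = s2_g / (s2_g + s2_e / nr)
#   across years:     R2 = s2_g / (s2_g + s2_gy / nl + s2_e / (nl nr))
# The BLUP of an accession mean in the balanced random-intercept structure
# shrinks its raw mean toward the grand mean by exactly this factor, so the
# shrinkage coefficient and the repeatability are one and the same number.

.check_vc_inputs <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals))) .stopf("variance components must be finite")
  if (any(vals < 0)) .stopf("variance components must be non-negative")
}

#' Accession-mean repeatability within a single year
#'
#' `R1 = sigma_g2 / (sigma_g2 + sigma_e2 / nr)`: the proportion of variance
#' among accession means (each averaging `nr` replicates) attributable to
#' genotype.
#'
#' @param sigma_g2 genotypic variance (trait units squared).
#' @param sigma_e2 residual variance (trait units squared).
#' @param nr number of replications per accession mean.
#' @return An object of class `repeatability` with fields `scope`, `value`,
#'   `nr` and `components`.
#' @examples
#' repeatability_single(0.211, 0.086, 3)
#' @export
repeatability_single <- function(sigma_g2, sigma_e2, nr) {
  .check_vc_inputs(sigma_g2, sigma_e2)
  if (!.is_count(nr)) .stopf("`nr` must be a positive integer")
  denom <- sigma_g2 + sigma_e2 / nr
  if (denom == 0) .stopf("undefined ratio: both variance components are zero")
  structure(
    list(scope = "single_year", value = sigma_g2 / denom,
         nl = 1L, nr = as.integer(nr),
         components = c(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2)),
    class = "repeatability")
}

#' Accession-mean repeatability across years
#'
#' `R2 = sigma_g2 / (sigma_g2 + sigma_gy2 / nl + sigma_e2 / (nl nr))`: the
#' proportion of variance among across-year accession means attributable to
#' genotype, with genotype-by-year interaction diluted by the number of
#' years `nl` and residual noise by the total replication `nl * nr`.
#'
#' @param sigma_g2 genotypic variance.
#' @param sigma_gy2 genotype-by-year interaction variance.
#' @param sigma_e2 residual variance.
#' @param nl number of years.
#' @param nr number of replications per year.
#' @return An object of class `repeatability`.
#' @examples
#' repeatability_across(0.058, 0.004, 0.004, nl = 2, nr = 3)
#' @export
repeatability_across <- function(sigma_g2, sigma_gy2, sigma_e2, nl, nr) {
  .check_vc_inputs(sigma_g2, sigma_gy2, sigma_e2)
  if (!.is_count(nl) || !.is_count(nr)) {
    .stopf("`nl` and `nr` must be positive integers")
  }
  denom <- sigma_g2 + sigma_gy2 / nl + sigma_e2 / (nl * nr)
  if (denom == 0) .stopf("undefined ratio: all variance components are zero")
  structure(
    list(scope = "across_years", value = sigma_g2 / denom,
         nl = as.integer(nl), nr = as.integer(nr),
         components = c(sigma_g2 = sigma_g2, sigma_gy2 = sigma_gy2,
                        sigma_e2 = sigma_e2)),
    class = "repeatability")
}

#' Repeatability from a fitted variance-component object
#'
#' Dispatches to [repeatability_single()] or [repeatability_across()] using
#' the components and design constants stored in the fit.
#'
#' @param vc a `varcomp_single` or `varcomp_across` object.
#' @return An object of class `repeatability`.
#' @export
repeatability <- function(vc) {
  stopifnot(inherits(vc, "varcomp"))
  if (inherits(vc, "varcomp_across")) {
    repeatability_across(vc$sigma_g2, vc$sigma_gy2, vc$sigma_e2, vc$nl, vc$nr)
  } else {
    repeatability_single(vc$sigma_g2, vc$sigma_e2, vc$nr)
  }
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("<repeatability> %s: R = %.4f (nl = %d, nr = %d)\n",
              x$scope, x$value, x$nl, x$nr))
  invisible(x)
}

#' BLUP of accession means for one trait
#'
#' In the balanced random-intercept structure the best linear unbiased
#' predictor of an accession effect is a uniform shrinkage of its raw mean
#' deviation: `g_i = lambda (ybar_i - ybar)` with `lambda` equal to the
#' accession-mean repeatability (R1 within a year, R2 across years, with the
#' across-years factor absorbing the genotype-by-year adjustment).  The BLUP
#' mean is `mu + g_i`, so the column mean is preserved and the spread of
#' accession means is contracted by `lambda`.
#'
#' @param ds a [trait_dataset()].
#' @param trait trait name.
#' @param vc variance components fitted on the same data slice
#'   ([fit_single_year()], [fit_across_years()] or [em_reml()]).
#' @return A list of class `blup_column` with fields `trait`, `values`
#'   (named vector of BLUP means), `shrinkage`, `grand_mean` and `scope`.
#' @export
blup_accession_means <- function(ds, trait, vc) {
  stopifnot(inherits(vc, "varcomp"))
  if (!identical(vc$trait, trait)) {
    .stopf("fit is for trait '%s', not '%s'", vc$trait, trait)
  }
  single <- inherits(vc, "varcomp_single")
  r <- .slice_trait(ds, trait, if (single) vc$year else NULL)
  if (nrow(r) == 0L) .stopf("no records for trait '%s'", trait)
  if (!single) {
    yrs <- sort(unique(r$year))
    fit_yrs <- sort(as.integer(names(vc$year_means)))
    if (!identical(yrs, fit_yrs)) {
      .stopf("fit used years {%s} but data slice has {%s}",
             paste(fit_yrs, collapse = ", "), paste(yrs, collapse = ", "))
    }
  }
  rep_obj <- repeatability(vc)
  lambda <- rep_obj$value
  acc <- ds$accessions[ds$accessions %in% r$accession]
  m_i <- tapply(r$value, factor(r$accession, levels = acc), mean)
  grand <- mean(r$value)
  vals <- grand + lambda * (as.numeric(m_i) - grand)
  structure(
    list(trait = trait, values = stats::setNames(vals, acc),
         shrinkage = lambda, grand_mean = grand,
         scope = rep_obj$scope),
    class = "blup_column")
}

#' Accession x trait matrix of BLUP-adjusted means
#'
#' Fits each trait under the requested scope and assembles the BLUP accession
#' means into a matrix in the dataset's trait order.  Across years this is
#' the accession x trait mean matrix adjusted for genotype-by-year
#' interaction effects, the input to all multi-trait analyses
#' ([phenotypic_correlation()], [pattern_analysis()]).
#'
#' @param ds a [trait_dataset()].
#' @param scope `"across_years"` (default) or `"single_year"`.
#' @param year required when `scope = "single_year"`.
#' @param method `"ems"` for the balanced expected-mean-squares fit or
#'   `"em_reml"` for the iterative fit (needed for unbalanced data).
#' @return An object of class `blup_matrix`: list with `values` (accession x
#'   trait matrix), `accessions`, `traits`, `grand_means`, `shrinkage`,
#'   `scope`, `year`.
#' @export
build_blup_matrix <- function(ds, scope = c("across_years", "single_year"),
                              year = NULL, method = c("ems", "em_reml")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  if (scope == "single_year" && is.null(year)) {
    if (length(ds$years) > 1L) .stopf("scope 'single_year' needs `year`")
    year <- ds$years
  }
  cols <- vector("list", length(ds$traits))
  names(cols) <- ds$traits
  failures <- character(0)
  for (tr in ds$traits) {
    res <- tryCatch({
      vc <- if (method == "em_reml") {
        em_reml(ds, tr, model = scope, year = year)
      } else if (scope == "single_year") {
        fit_single_year(ds, tr, year)
      } else {
        fit_across_years(ds, tr)
      }
      blup_accession_means(ds, tr, vc)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s (%s)", tr, conditionMessage(res)))
    } else {
      cols[[tr]] <- res
    }
  }
  if (length(failures)) {
    .stopf("BLUP fit failed for trait(s): %s", paste(failures, collapse = "; "))
  }
  values <- do.call(cbind, lapply(cols, `[[`, "values"))
  dimnames(values) <- list(ds$accessions, ds$traits)
  structure(
    list(values = values, accessions = ds$accessions, traits = ds$traits,
         grand_means = vapply(cols, `[[`, numeric(1L), "grand_mean"),
         shrinkage = vapply(cols, `[[`, numeric(1L), "shrinkage"),
         scope = scope, year = if (scope == "single_year") as.integer(year)),
    class = "blup_matrix")
}

#' @export
print.blup_matrix <- function(x, ...) {
  cat(sprintf("<blup_matrix> %d accessions x %d traits (%s%s)\n",
              nrow(x$values), ncol(x$values), x$scope,
              if (!is.null(x$year)) paste0(" ", x$year) else ""))
  print(round(x$values, 4))
  invisible(x)
}

#' @export
as.matrix.blup_matrix <- function(x, ...) x$values
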