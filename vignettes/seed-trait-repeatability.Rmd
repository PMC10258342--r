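---
title: "Variance components, repeatability and pattern analysis of seed-trait trials"
author: "seedvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance components, repeatability and pattern analysis of seed-trait trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedvar)
```

## The problem

Germplasm collections of wild or semi-domesticated plants are routinely
characterized by measuring quantitative seed-morphology traits — perimeter,
length, width, thickness, hilum dimensions, shape ratios, 100-seed weight —
on a set of accessions (seed samples, one per collection site) over
replicated scans in one or more harvest years.  Two questions drive the
analysis:

1. **How much of the observed variation is genetic?**  Answered by variance
   components and by the *repeatability of accession means* — the fraction
   of the variance among accession means attributable to genotype, an upper
   bound on the broad-sense heritability of those means.
2. **Which accessions resemble each other, and which traits co-vary?**
   Answered by *pattern analysis*: hierarchical clustering plus a
   principal-component biplot of a standardized accession-by-trait matrix
   of BLUP means.

`seedvar` implements this workflow for the canonical balanced layout
(a accessions x nl years x nr replicates per trait) and, through an EM-type
REML fit, for unbalanced data as well.

## Models

Within one year the model for trait value $y_{ik}$ of accession $i$,
replicate $k$, is the one-way random-effects model

$$y_{ik} = \mu + g_i + \varepsilon_{ik}, \qquad
  g_i \sim N(0, \sigma^2_g), \quad
  \varepsilon_{ik} \sim N(0, \sigma^2_\varepsilon).$$

Across years the mixed model adds a fixed year effect $Y_j$ and a random
genotype-by-year interaction:

$$y_{ijk} = \mu + Y_j + g_i + (gY)_{ij} + \varepsilon_{ijk}, \qquad
  (gY)_{ij} \sim N(0, \sigma^2_{gy}).$$

Year is fixed rather than random because the target quantity — repeatability
of accession means — contains no year-variance term: two specific harvest
years are conditions of the trial, not a sample from a population of years.

### Estimation

On balanced data the expected mean squares give the closed-form solution
(`fit_single_year()`, `fit_across_years()`):

$$\hat\sigma^2_\varepsilon = MS_e, \qquad
  \hat\sigma^2_{gy} = (MS_{gy} - MS_e)/n_r, \qquad
  \hat\sigma^2_g = (MS_g - MS_{gy})/(n_l n_r),$$

which coincides with REML whenever the solution is interior.  Negative
moment solutions are clamped at zero and flagged (`truncated`); the clamped
value feeds everything downstream, with no re-solving of a reduced model.
Standard errors use the large-sample mean-square variance
$\mathrm{Var}(MS) = 2\,MS^2/df$ propagated through the linear combination;
the REML path instead inverts the expected information at convergence.
Both are large-sample approximations of the same quantity and agree closely
on balanced data.

For unbalanced data `em_reml()` runs the classical EM formulation of REML on
Henderson's mixed-model equations.  Each iteration solves the equations,
updates every variance component from the conditional expectation of its
sum of squares, and provably never decreases the restricted log-likelihood;
estimates are non-negative by construction.  Defaults: convergence when no
component moves more than `tol = 1e-8` between iterations, `max_iter =
10000`, initialization at the method-of-moments solution floored at
$10^{-6}\,\mathrm{var}(y)$ (equal split of the total variance when no
moment solution exists).

### Significance of genotypic variation

`lrt_genotype()` compares the restricted likelihoods of the model with and
without the genotype term (identical fixed effects, so the REML contrast is
valid).  Because the null value $\sigma^2_g = 0$ sits on the boundary of the
parameter space, the likelihood-ratio statistic is referred to the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$: $p = \tfrac12 P(\chi^2_1 \ge LR)$,
with $p = 1$ when $LR = 0$.  On balanced data both likelihoods are
maximized exactly in closed form: the restricted likelihood factorizes over
ANOVA strata, and the non-negativity constraints amount to pooling adjacent
strata whose mean squares violate their expected ordering
(pool-adjacent-violators).  At the trial scale used throughout this package
(15 accessions, 3 replicates) the exact size of the resulting 5% test is
0.046, and the Monte-Carlo calibration in the test suite confirms it.

### Repeatability and BLUP

Accession-mean repeatability within a year and across years:

$$R_1 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_\varepsilon/n_r},
\qquad
R_2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{gy}/n_l +
       \sigma^2_\varepsilon/(n_l n_r)}.$$

In the balanced random-intercept structure the BLUP of an accession effect
is a uniform shrinkage of its raw mean deviation,
$\hat g_i = \lambda(\bar y_i - \bar y)$, and the shrinkage factor $\lambda$
*is* the corresponding repeatability — the package asserts this identity to
machine precision rather than assuming it.  The across-years factor divides
the interaction variance by $n_l$, which is precisely what "adjusting the
accession-by-trait mean matrix for genotype-by-year effects" means here.
`build_blup_matrix()` assembles one shrunken column per trait; column means
equal the grand means and column spreads are contracted by $\lambda \in
[0, 1]$.

A consequence worth knowing: when a trait's $\hat\sigma^2_g$ clamps to zero,
its BLUP column is exactly constant and carries no accession information.
Accession-level correlations and standardized scores are undefined for such
a column, so `run_pipeline()` excludes those traits from the correlation
and pattern stages (they stay in the univariate outputs) and lists them in
the run manifest; the lower-level functions are stricter and refuse constant
columns outright.

## Association and pattern analysis

`phenotypic_correlation()` computes Pearson correlations of the BLUP means
over accessions, with two-sided p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom and stars at 0.05
and 0.01, with no multiple-testing correction — the convention of the
germplasm-characterization literature this package serves.  The estimator
operates on $n$ = number of accessions (15 in the reference layout), so
p-values are coarse; treat the stars as descriptive.  An alternative
variance-components estimator (genotypic plus residual covariance from the
multivariate mean cross-products) is available for single-year data as
`phenotypic_correlation_components()`; it uses replicate-level information
but admits no exact small-sample test, so it reports coefficients only.
`sscp_strata()` exposes the underlying MANOVA sums of cross-products
(between-accession versus residual, after removing year means as fixed
effects), whose diagonal reproduces the univariate mean squares.
`env_correlation()` applies the same correlation conventions to
per-accession site covariates such as altitude or growing-season
temperatures.

`pattern_analysis()` standardizes each BLUP column to mean 0, sd 1
(denominator $n-1$), then:

* **PCA** on the correlation matrix of the standardized values — traits are
  on incommensurable scales (mm, g, ratios), so the correlation metric is
  the only defensible choice.  Scores are $z V$, loadings are eigenvectors
  scaled by $\sqrt{\lambda_c}$, and each component's share of total
  variation is $100\,\lambda_c/\sum\lambda$.  Eigenvector signs follow a
  fixed rule (the largest-magnitude loading of each component is made
  positive, ties to the earliest trait) so biplots are identical across
  platforms.
* **Clustering** of accessions by Ward's minimum-variance linkage on
  Euclidean distances (`hclust` method `ward.D2`), cut to exactly `k`
  groups.  Ward is the standard in the pattern-analysis tradition; other
  linkages can be requested.  `k` is a user choice — typical analyses
  truncate at two or three groups after inspecting the dendrogram — and no
  automatic selection is attempted.  Group ids are relabelled 1..k by first
  appearance in accession order, and tie-breaking among equal-height merges
  follows `hclust`'s deterministic rule.
* **Group means** of the BLUP values in original units, with group sizes.

## The synthetic generator

`simulate_dataset()` draws from exactly the structure the estimators
assume: fixed year offsets, accession effects drawn jointly across traits
from a zero-mean multivariate normal with covariance
$D_{\sigma_g}\,\rho\,D_{\sigma_g}$, and independent normal interaction and
residual draws.  The cross-trait correlation applies to the genotypic
effects only; interaction and residual draws are trait-independent, the
simplest structure that reproduces realistic phenotypic correlation
matrices.  All draws come from a single seeded stream in a fixed documented
order (genotype block first, then per trait interaction and residual
blocks), so one seed yields one dataset bit for bit; zero-variance
components still consume their draws, keeping datasets comparable across
nested configurations.

The defaults mirror the reference trial design: 15 accessions, years 2014
and 2019, three scanned replicates of 100 seeds per accession and year,
nine traits.  `demo_trial_config()` fixes per-trait means (e.g. perimeter
14.778 mm, 100-seed weight 0.830 g), variance components, opposite-signed
year offsets, and a genetic correlation matrix with a strongly positive
size/weight complex (perimeter, length, width, thickness, 100-seed weight)
and a hilum shape ratio negatively related to it, projected to the nearest
positive semi-definite correlation matrix.  What the generator does *not*
emulate: seed-level measurement error within a scanned batch (the model
operates on replicate means), non-Gaussian trait distributions, spatial or
maternal-environment structure, and correlated interaction or residual
draws.  Passing tests therefore demonstrate correctness of the estimators
under their own assumptions, not robustness to violations of them.

`recovery_experiment()` repeats simulate-and-fit cycles and aggregates bias
and spread of every component and of $R_2$; at the reference scale
(15 x 2 x 3, $\sigma^2_g = 0.2$, $\sigma^2_{gy} = 0.05$,
$\sigma^2_\varepsilon = 0.1$, 300 replicates) mean $\hat\sigma^2_g$ lands
within 0.02 of truth and mean $\hat R_2$ within 0.05, which is what the
acceptance suite asserts.

## Numerical choices

* The EM residual quadratic form is evaluated as
  $e'e + \mathrm{sol}' D\,\mathrm{sol}$ rather than the algebraically equal
  $y'y - \mathrm{sol}'W'y$, which cancels catastrophically on
  near-noiseless data.
* Components falling below $10^{-6}\,\mathrm{var}(y)$ are pinned at exactly
  zero and flagged: EM approaches a boundary only sublinearly, and a
  variance a millionth of the total is scientifically zero.
* A residual variance collapsing below the same band ends the iteration
  (perfect-fit data; the optimum is on the boundary).
* Near-singular mixed-model equations (the same degenerate limit) receive a
  progressively escalating ridge before Cholesky factorization.
* CSV output writes doubles with 17 significant digits, the smallest count
  that round-trips IEEE doubles exactly; `write_trait_table()` followed by
  `read_trait_table()` is the identity, byte for byte on re-write.

## Problem sizes in the test and acceptance runs

The shipped suites use sizes chosen to make Monte-Carlo assertions sharp at
interactive cost: 100 random designs of 5-30 accessions for the EM-versus-
moments equivalence sweep, 300 recovery replicates at the 15 x 2 x 3
reference scale, 2000 null replicates for the test-size calibration, 1000
random component sets for the shrinkage identity, and single datasets of
200-5000 accessions for generator moment checks.  All are regenerated from
code at run time; the package ships no data files.

## Known limitations

* The EMS path requires balance; it refuses unbalanced slices and points to
  `em_reml()` rather than silently approximating.
* Standard errors of variance components are large-sample approximations;
  with 14 genotype degrees of freedom they are rough guides, not test
  statistics.
* The across-years model assumes a common residual variance across years
  and no covariates; heterogeneous-variance and covariate extensions are
  out of scope.
* Correlation p-values are unadjusted for multiplicity by design.
* EM convergence near an interior optimum is linear; extremely
  ill-conditioned designs may need a larger `max_iter`.
* Replicates index scan batches, not blocks: no operation matches replicate
  labels across accessions.
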