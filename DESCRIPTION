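Package: seedvar
Title: Variance Components, Repeatability and Pattern Analysis for Seed-Trait
    Germplasm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating quantitative seed-morphology traits measured
    on germplasm accessions in replicated multi-year trials: balanced-design
    variance-component estimation by expected mean squares, EM-type residual
    maximum likelihood (REML) for general designs, accession-mean repeatability
    within and across years, best linear unbiased prediction (BLUP) of
    accession means adjusted for genotype-by-year effects, phenotypic and
    trait-environment correlation matrices with significance tests, MANOVA
    sums of cross-products, and pattern analysis (Ward clustering combined
    with a principal-component biplot) of standardized accession-by-trait
    matrices.  A synthetic trial generator with cross-trait genetic
    correlations supports power and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
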