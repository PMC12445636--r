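Package: semenvc
Title: Variance Components and Age Effects for Longitudinal Boar Semen Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pedigree-based animal repeatability models for longitudinal
    boar semen records. Provides relationship-matrix algebra (inbreeding,
    dense A, sparse A-inverse), restricted maximum likelihood estimation of
    variance components by expectation-maximisation with average-information
    acceleration, both for the single-trait repeatability model and for a
    trivariate age-class model with cross-class additive-genetic and
    permanent-environment covariances, genetic parameters (heritability,
    repeatability, correlations) with delta-method standard errors,
    predicted marginal age effects that correct for phenotype-based culling
    of boars, and a synthetic-data generator with which every stage can be
    verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
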