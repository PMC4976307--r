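Package: fidherit
Title: Heritability of Flight Initiation Distance from Pedigreed Wild Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of flight initiation distance (FID),
    a field measure of fear of humans, in pedigreed wild bird populations
    sampled across urban and rural habitats. Provides pedigree validation and
    additive (numerator) relationship matrices with their sparse inverses,
    heritability from midparent and single-parent offspring regressions of
    log-FID with full-sib brood averaging and the (1 + r) correction for
    phenotypic assortative mating, z-score comparison of heritability
    estimates, a Bayesian animal model fitted by a Gibbs sampler (habitat and
    sex as fixed effects, additive genetic and residual variances, posterior
    heritability with highest-posterior-density intervals), and a synthetic
    pedigree-and-phenotype generator that emulates the sampling design of a
    multi-generation urban/rural study for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
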