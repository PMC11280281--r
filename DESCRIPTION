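Package: matherit
Title: Bayesian Variance Partitioning for Maternally Influenced Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based animal models for partitioning the variance of
    maternally influenced traits into direct additive, maternal genetic
    (with a direct-maternal covariance) and maternal permanent
    environmental components. Models are fitted by Gibbs sampling with a
    compiled single-site sampler, compared by the deviance information
    criterion, and summarised as posterior heritabilities, maternal
    fractions and genetic and environmental correlations with highest
    posterior density intervals and convergence diagnostics. Includes
    pedigree renumbering, numerator relationship matrix construction
    (direct and inverse, with inbreeding), outlier screening, and a
    synthetic pedigreed-population generator for hierarchical sire-dam
    mating designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
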