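Package: hlmrp
Title: Multilevel Regression with Post-Stratification for Local Health
    Literacy Determinants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates local-population determinants of binary
    health-literacy outcomes by Bayesian multilevel logistic regression
    with post-stratification (MRP).  A source skills survey provides
    individual-level outcomes; the target population's covariate
    distribution is assembled from heterogeneous local sources via joint
    estimation from microdata, iterative proportional fitting (raking),
    and small-area deprivation tables.  Counterfactual average treatment
    effects over the post-stratified population (MRP-ATE) quantify each
    determinant, and determinants are prioritised probabilistically via
    cumulative rank probabilities and SUCRA.  Includes a synthetic-data
    generator that emulates all input surveys from a known multilevel
    logistic process, and a compiled Polya-Gamma Gibbs sampler for the
    multilevel model.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    lme4,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
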