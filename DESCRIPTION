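Package: otcpkpd
Title: Population Pharmacokinetics and PK/PD Cutoff Simulation for
    Oxytetracycline in Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for population-pharmacokinetic analysis of long-acting
    oxytetracycline in calves and adult cattle: a three-compartment
    disposition model with dual first-order absorption and lag, an
    age-covariate population model with two full between-subject
    variance-covariance blocks, Monte-Carlo simulation of free-drug
    exposure (fAUC/MIC), probability-of-target-attainment tables and
    PK/PD cutoff determination on a two-fold MIC dilution series, a
    Laplace nonlinear mixed-effects estimator with BIC-based covariate
    selection and subject-level bootstrap, visual predictive checks,
    and a synthetic multi-source study generator with below-LLOQ (M1)
    censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
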