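Package: hdclamp
Title: Interactive Psychometrics with a Human Dynamic Clamp Virtual Partner
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for human dynamic clamp (HDC)
    interactive psychometrics. Simulates bidirectionally coupled
    human-virtual-partner movement dyads from a hybrid nonlinear oscillator
    model with Haken-Kelso-Bunz (HKB) coupling, generates synthetic
    case-control cohorts running the 40-trial in-phase/anti-phase protocol
    with cooperative and competitive virtual-partner behavior, computes the
    five normalized interpersonal-synchrony scores (motor, coordination,
    task, intention, humanness), age-corrects them with Gaussian-process
    normative modeling, and reproduces the downstream statistical battery:
    demographics tests, developmental correlations, normative group
    comparisons, coded-covariate subcondition regressions, hierarchical
    stratification, and cross-validated classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mclust,
    pROC,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
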