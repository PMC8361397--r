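Package: antddm
Title: Hierarchical Drift-Diffusion Modelling of the Attention Network Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of two-choice
    conflict tasks with the drift-diffusion model. Provides exact Wiener
    first-passage-time densities and closed-form validation quantities, a
    synthetic-cohort generator emulating the Attention Network Task (trial
    schedules, clinical group structure, trial-wise brain-network covariates
    coupled to drift rate, and raw network BOLD runs), hierarchical MCMC
    estimation with condition-dependent drift and boundary, deviance
    information criterion model comparison, posterior predictive checks,
    Bayesian posterior-overlap hypothesis tests, and single-trial beta-series
    estimation from network-averaged BOLD time courses with motion and DVARS
    quality control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    withr,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
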