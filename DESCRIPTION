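Package: riskshift
Title: Bayesian Psychometric Analysis of Stimulation Effects on Risky Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-alternative forced-choice risk tasks run
    under blocked on/off brain-stimulation designs. Provides a seeded task
    simulator with a parametric choice agent, a four-parameter logistic
    psychometric model (threshold, slope, floor, ceiling) with a Bernoulli
    likelihood, a self-contained adaptive random-walk Metropolis sampler with
    split-Rhat and effective-sample-size diagnostics, posterior
    threshold-shift inference with posterior-predictive fit classification,
    per-risk-level mid-P Fisher exact tests, a factorial Type II reaction-time
    ANOVA, and an end-to-end reproducible pipeline over trial-log CSV files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    car,
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
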