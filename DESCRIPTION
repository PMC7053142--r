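Package: dropoutsim
Title: Simulation of Longitudinal Binary Trials with Dropout: Chi-Squared
    versus Mixed-Model Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulation pipeline for two-arm longitudinal
    randomized controlled trials with repeated binary outcomes. Generates
    correlated outcomes through a Beta-distributed subject-level event
    probability, imposes missing-completely-at-random or missing-at-random
    dropout at the final visit at calibrated per-arm rates, analyzes each
    replicate with a complete-case Pearson chi-squared test (2x2-table
    log-odds ratio) and with a random-intercept logistic generalized linear
    mixed model fitted by restricted pseudo-likelihood, and aggregates
    replicates into power, type I error, relative bias, coverage and
    standard-error diagnostics with Monte Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    nlme,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
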