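Package: invadyn
Title: Mutual Invasibility Analysis of Microbiome-Modified Competition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for mutual-invasibility experiments on
    phytoplankton (or other microbial) species pairs grown with and without
    their associated bacterial communities.  Estimates per-capita growth
    rates from density time series (two-point rates, rolling log-linear
    regression, logistic fits, polynomial model selection), computes the
    sensitivity-to-interaction statistic S_i = (mu_alone - mu_invading) /
    mu_alone, derives niche and relative fitness differences with a
    coexistence classification, and provides the hypothesis-testing layer
    (two-way ANOVA, t tests, isolate-panel ANOVA).  A seeded Lotka-Volterra
    simulator with hemocytometer-style Poisson count noise generates
    complete synthetic invasion experiments with known ground truth so that
    every stage of the pipeline can be verified by parameter recovery.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
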