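Package: funcdiv
Title: Growth, Scaling, and Calibration of Function Diversity in Complex Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how the number of distinct functions
    (occupations in organizations and cities, expressed proteins in
    microbes) grows with system size. Implements a generalized Yule-Simon
    growth process in which the probability of creating a new function
    depends on the existing abundance distribution through a
    diversification exponent, and newcomers join existing functions by
    nonlinear preferential attachment governed by a specialization
    exponent. Provides mean-field diversity predictions for the analytic
    limits, power-law (Heaps' law) and logarithmic diversity-size fits
    with AIC-based model selection, normalized rank-frequency analysis
    with a log-space distance, simulation-based calibration of the two
    exponents by differential evolution, a parameter-recovery harness,
    synthetic fixture generation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
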