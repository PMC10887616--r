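Package: cubinar
Title: Circumstance-Driven Bivariate INAR(1) Models for Count Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, estimation and diagnostics for the
    circumstance-driven bivariate integer-valued autoregressive model of
    order one (CuBINAR(1)), a non-stationary model for paired low-count
    time series whose marginal means switch with an observed categorical
    regime ("circumstance") sequence. Provides the bivariate Poisson
    distribution machinery, Markov-chain regime generators, exact
    simulation via binomial thinning, Yule-Walker and conditional
    maximum likelihood estimation with approximate standard errors, and
    model-adequacy tools (Pearson residuals, non-randomized PIT
    histograms, logarithmic score, AIC, in- and out-of-sample RMSE),
    together with a Monte-Carlo study harness and a small command-line
    front-end. The stationary bivariate Poisson INAR(1) model is
    included as the single-regime special case.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
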