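Package: oscbranch
Title: Branching Processes with Oscillating Extinction Rates for Neuronal Avalanches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-time binary branching processes whose extinction rate
    oscillates sinusoidally in time, a minimal model of neuronal avalanches
    co-existing with brain-wave-like oscillations. Provides an exact
    event-driven stochastic simulator (Ogata-style thinning), closed-form and
    first-order perturbative observables (moments, factorial moments,
    two-time covariance, survival probability, avalanche-duration density,
    ultimate survival, duration-averaged avalanche shape), a non-perturbative
    probability-generating-function oracle based on backward Riccati-type
    ODEs, and ensemble estimators (moments with standard errors, empirical
    survival, duration/size power-law exponent fits, termination-time
    conditioned avalanche shapes). All results are returned as tibbles and
    plotted with ggplot2.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
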