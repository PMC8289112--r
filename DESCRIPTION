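Package: locustform
Title: Continuum Modelling of Locust Group Formation Under Heterogeneous Food
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of a one-dimensional nonlocal
    advection-diffusion-reaction model of locust phase polyphenism, in which
    solitarious and gregarious densities interact through exponential social
    potentials, deplete a food field, and switch phase at density-dependent
    rates. Provides a conservative finite-volume solver (first-order upwind
    advection, spectral convolution of the social potentials, central-difference
    diffusion, adaptive Dormand-Prince time stepping in compiled code), the
    model's closed-form analytics (large- and small-mass aggregate profiles,
    linear-stability thresholds for group formation, time-to-formation
    estimates, the gradient-flow energy), and the numerical-experiment layer
    (noisy initial conditions, smoothed-step food patches, parameter sweeps
    with group-formation classification, and per-capita foraging-advantage
    metrics).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
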