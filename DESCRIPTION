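Package: aeroband
Title: Aerotactic Band Formation in Capillary Oxygen Gradients
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic one-dimensional model of aerotactic band formation
    by motile bacteria in a capillary oxygen gradient. Couples hyperbolic
    transport equations for right- and left-swimming cells, whose reversal
    frequencies switch at threshold oxygen concentrations, to oxygen diffusion
    with bacterial consumption. Provides a conservative upwind finite-volume
    integrator with adaptive stable time stepping, full-width-at-half-maximum
    band detection with oxygen readouts at the band sides, one-at-a-time
    parameter sensitivity sweeps, and an exhaustive grid search that identifies
    the four oxygen switch thresholds from a measured band location and width.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
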