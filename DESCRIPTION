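Package: fcspipe
Title: Simulation, Correlation and Model Fitting for Confocal Fluorescence
    Correlation Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for confocal fluorescence correlation
    spectroscopy (FCS) of fluorescently tagged proteins in cells and live
    embryos. Simulates photon-count traces from Brownian dynamics in a 3D
    Gaussian observation volume (free diffusion, two-component mixtures,
    triplet-like blinking, directed flow, rare bright aggregates), computes
    multi-tau autocorrelation functions with segment-wise uncertainties, fits
    one- and two-component 3D diffusion models with optional photophysics and
    diffusion-plus-flow models by weighted nonlinear least squares, selects
    among nested candidate models by F-test with BIC fallback, derives
    diffusion coefficients, flow velocities and molecular brightness, and
    aggregates per-measurement fits into cohort summaries, Student's t-tests
    and intensity-versus-particle-number brightness regressions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
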