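Package: vegpattern
Title: Stochastic Formation and Spectral Analysis of Vegetation Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates nonlinear reaction-advection-diffusion models of
    dryland vegetation (a single-species grazing model and the Rietkerk
    scale-dependent feedback model) on periodic grids with spatially
    correlated log-normal environmental heterogeneity, quantifies the
    emerging patterns spectrally (characteristic wavelength, regularity,
    cut-off wavelength, spectral coherence, transfer functions, and a
    surrogate-based periodicity test), and synthesizes statistically
    equivalent patterns with parametric linear filters (higher-order
    low-pass, band-pass, and a noisy-oscillator model for banded
    patterns).  Filter families are fitted to empirical spectral
    densities by minimizing the Hellinger distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
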