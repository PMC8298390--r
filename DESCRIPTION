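Package: dropmix
Title: Stochastic Mixing Simulations and Spectral Analysis for Drop-on-Drop Serial Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing drop-on-drop mixing experiments in
    time-resolved serial crystallography. Provides a compartmental kinetic Monte
    Carlo (Gillespie) engine for reaction-diffusion and mass-flow simulations of
    picoliter substrate drops merging with nanoliter crystal-bearing drops,
    closed-form and ODE oracles for competitive calcium-dye binding, linear
    spectral unmixing of fluorescence spectra with exponential rise-time fitting,
    a synthetic-data generator for the calcium-indicator validation experiment,
    and exact arithmetic for merged concentrations, delay times and substrate
    consumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
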