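Package: alexfret
Title: Conformational-State Analysis of ALEX Single-Molecule FRET Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for surface-immobilised single-molecule FRET
    recorded with alternating-laser excitation (ALEX). Simulates three-channel
    intensity traces with realistic photophysics (spectral crosstalk, direct
    excitation, detection-efficiency imbalance, single-step photobleaching),
    applies rule-based trace quality control, estimates the alpha/beta/gamma/delta
    correction factors and converts raw intensities to absolute FRET efficiency
    and stoichiometry, infers conformational-equilibrium states by
    unbinned-likelihood Gaussian mixture fitting with BIC model selection,
    converts efficiencies to inter-dye distances via the Forster relation,
    detects dynamic transitions with per-trace hidden Markov models and
    donor-acceptor cross-correlation, samples accessible-volume dye positions on
    protein structures, and fits bounded Hill dose-response curves with the
    accompanying ANOVA/Tukey significance procedure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    minpack.lm,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
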