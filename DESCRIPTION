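Package: erpauth
Title: Multi-Scale 3D Convolutional Networks for ERP-Based EEG Identity
    Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for event-related-potential (ERP) based EEG identity
    authentication. Converts multichannel oddball-task EEG into a
    spatial-temporal-frequency 16 x 94 x 60 tensor via short-time Fourier
    spectrograms, builds single-scale and multi-scale (inception-style)
    convolutional networks in 1D/2D/3D from declarative specifications,
    and evaluates authentication accuracy under within-subject stratified
    cross-validation and repeated disjoint cohort splits. Includes a
    synthetic oddball name-task EEG generator (P200/P300/late-negativity
    components, pink noise, line noise, ocular artifacts), the full
    preprocessing chain (Chebyshev band-pass, resampling, re-referencing,
    ICA artifact removal, epoching, baseline and blank-trial correction),
    receptive-field calibration tables, and desk-scale experiment drivers
    (kernel sweeps, multi-scale strategy comparison, branch-by-depth grids,
    feature heat maps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
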