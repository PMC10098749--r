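Package: boldcascade
Title: Two-Stage Multitask Classification of fMRI BOLD Signals with Fused
    Spectral and Deep Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies 1-D task-fMRI BOLD time series in two stages: a task
    stage (emotion, memory, motor, resting) followed by a sub-phase stage
    (high/medium/low social support; encode/recall). Each stage uses a
    feature fusion module that concatenates hand-crafted frequency features
    (FFT summary statistics and multilevel discrete wavelet coefficients),
    convolutional features of continuous-wavelet scalogram images from a
    50-layer residual network, and recurrent features from a two-layer LSTM
    encoder; fused vectors are reduced by minimum-redundancy
    maximum-relevance (MRMR) selection and classified by a two-layer
    fully-connected network. Includes a block-design BOLD signal simulator
    (boxcar convolved with a double-gamma haemodynamic response plus AR(1)
    noise and drift), grouped cross-validation, classification metrics, and
    pairwise classifier-diversity tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    EBImage,
    grDevices,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
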