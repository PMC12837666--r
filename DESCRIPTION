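Package: spasmfusion
Title: Dual-Stream EEG-EMG Fusion Networks for Detecting Infantile Epileptic Spasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements a dual-stream neural architecture for detecting epileptic
    spasms in synchronized multichannel EEG and surface EMG recordings of infants
    with infantile epileptic spasms syndrome (West syndrome). Each modality is
    encoded by a continuous-wavelet-transform scalogram front end over
    physiological frequency bands, a spatio-temporal convolution block, and a
    bidirectional selective state-space (Mamba-style) sequence model; the two
    streams are fused by a linear recurrent cross-modal attention layer with
    RWKV-style weighted key-value recurrence. The package provides the full
    preprocessing, windowing and subject-wise evaluation protocol, a seeded
    synthetic cohort generator that emulates the statistical structure of
    clinical spasm recordings (slow-wave/spike complexes, electrodecremental
    attenuation, lagged EMG bursts, pink background noise, line noise and motion
    artifacts), hand-written forward and backward passes with Adam training,
    classification metrics with ROC/AUC, and analytic parameter and FLOP
    accounting for every module.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
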