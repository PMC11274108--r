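Package: msslwear
Title: Multi-Shared-Task Self-Supervised CNN-LSTM Estimation of UPDRS-III
    Motor Scores from Wearable Gyroscopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Unified Parkinson's Disease Rating Scale Part III
    (UPDRS-III) motor severity from wrist and ankle gyroscope recordings
    captured during free-living activities. Implements the full pipeline:
    band-pass FIR filtering, 5 s windowing and Kaiser-window spectrograms;
    self-supervised pretext tasks (rotation, permutation, time warping) with
    a multi-shared-task loss; a multichannel CNN-LSTM that fuses raw-signal
    and spectrogram branches; transfer learning with frozen early
    convolutional blocks and Huber-loss fine-tuning; leave-one-subject-out
    evaluation with round-averaged Pearson r, R-squared, MAE and RMSE; and a
    synthetic Parkinson's cohort simulator with severity-dependent tremor
    and bradykinesia for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
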