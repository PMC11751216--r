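Package: neurochoice
Title: Multimodal Consumer-Choice Prediction from EEG and Eye Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for predicting consumer buy/no-buy decisions
    from simultaneously recorded electroencephalography (EEG) and eye-tracking
    (ET) streams. Implements EEG cleaning (zero-phase Butterworth band-pass,
    Artifact Subspace Reconstruction, wavelet-threshold transient removal),
    gaze preprocessing (blink-gap interpolation, I-DT fixation detection,
    64x64 gaze-plot rasterization), handcrafted features (signal statistics,
    Welch band powers, discrete-wavelet-transform coefficient statistics,
    fixation/saccade measures), supervised deep feature extractors (a
    CNN-LSTM for EEG windows and LeNet-5 for gaze plots, trained with Adam),
    feature-level fusion, SMOTE class balancing, and a stacking ensemble
    (random forest, gradient boosting, XGBoost base learners with a random
    forest meta learner) evaluated under stratified cross-validation. A
    synthetic multimodal data generator with controllable class effects and
    artifact rates makes the full pipeline testable without proprietary
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    ranger,
    Rcpp,
    signal,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
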