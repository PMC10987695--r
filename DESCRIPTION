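Package: segvoice
Title: Continuous Emotion Classification from Fixed-Window Voice Segments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying basic emotions (fear, joy, anger, disgust,
    sadness, neutral) from short, uniformly segmented voice recordings.
    Implements fixed 1.5 s window segmentation with symmetric trim/pad, a
    14,244-entry acoustic feature battery (windowed signal variance,
    harmonic-percussive separation, framewise spectral descriptors, pitch
    tracking, chroma, tonnetz, MFCCs and bin-wise spectrogram statistics),
    320x240 RGB mel-spectrogram rendering, three seeded neural classifier
    designs (feedforward, convolutional, and a hybrid of both), Gaussian
    process hyperparameter search, and a Bayesian evaluation stack:
    stratified cross-validation with balanced accuracy, Independent
    Validation with sequential beta-posterior updating, posterior overlap
    and exceedance comparisons against chance and against human raters, and
    saliency/Shapley time-segment attribution. A synthetic emotional-voice
    generator makes the full pipeline reproducible without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    png,
    jsonlite,
    lhs,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
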