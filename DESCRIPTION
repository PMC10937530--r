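Package: cogload
Title: Cognitive-Load Features from EEG, Autonomic Signals, and n-Back Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A feature-extraction and analysis pipeline for multi-modal
    cognitive-load experiments. Computes normalized alpha and theta band-power
    time series from frontal EEG by sliding-window Welch spectral estimation,
    quantifies infra-slow (64-128 s period) rhythmic fluctuations of alpha
    power, derives heart-rate variability (RMSSD) from photoplethysmography,
    counts skin-conductance responses from electrodermal activity, scores
    zero-back and three-back working-memory tasks (accuracy, reaction-time
    mean, interquartile range and low-frequency fluctuation spectrum), trains
    and applies a Gaussian-kernel support-vector-machine arousal-state
    estimator with leave-one-person-out cross-validation, and runs the
    paired-comparison and difference-score correlation statistics with
    Benjamini-Hochberg correction. Seeded generators produce synthetic
    multi-modal sessions with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
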