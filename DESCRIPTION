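Package: monoseize
Title: Patient-Specific Single-Channel EEG Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific seizure detection on long-term scalp EEG with
    progressive channel reduction (18-channel longitudinal bipolar montage,
    4 wearable-candidate channels, single channel). Provides EDF input/output,
    bipolar montage derivation, 1-30 Hz band-pass preprocessing, 4-s window
    segmentation with class-balanced batch sampling, a parallel two-branch
    convolutional network classifier emitting ictal probabilities, event-level
    detection on continuous recordings (Savitzky-Golay probability smoothing,
    threshold/run-length extraction, interval merging) scored by event
    sensitivity, false-alarm rate and onset latency, a file-wise k-fold
    patient-specific evaluation protocol, and a synthetic-EEG generator with
    spatially localized rhythmic seizures for fully reproducible experiments.
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
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
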