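Package: edfviz
Title: Headless Toolkit for Multi-Channel EEG Prediction Overlay and
    Seizure-Detection Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Reads, writes, de-identifies and augments EDF/EDF+ scalp EEG
    recordings (including the time-stamped annotation channel); derives
    referential and longitudinal bipolar 10-20 montages; filters, resamples
    and summarises signals (mean, variance, line length, canonical band
    power, spectrogram); aligns, smooths and thresholds window-wise
    classifier predictions; renders stacked traces with prediction shading
    and topographic scalp maps; and evaluates seizure detectors with
    false-positive-budget threshold calibration, window-level AUCs and
    event-level sensitivity, false-positive duration and onset latency.
    Ships a synthetic 10-20 EEG generator so every step is exercisable
    without clinical data, and a command-line interface for batch use.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
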