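Package: rppgfatigue
Title: Multi-Modal Driver Fatigue Detection from Remote Photoplethysmography and Facial Landmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A contact-free pipeline for driver fatigue detection from
    remote photoplethysmography (rPPG) traces and facial landmark streams. Extracts
    region-of-interest intensity traces, separates the blood-volume pulse with
    singular spectrum analysis followed by moving-average detrending and Hamming
    FIR bandpass filtering, detects pulse peaks with an improved Pan-Tompkins
    detector (Shannon energy envelope, adaptive dual thresholds, refractory period
    and search-back), derives time- and frequency-domain heart-rate-variability
    features (mean, SD, Welch LF/HF), computes PERCLOS and yawn-rate features from
    five-point landmark geometry, and fuses per-window decisions from two 1-D
    convolutional classifiers through a bidirectional LSTM. Includes a fully
    ground-truthed synthetic-signal generator so every stage is testable end to
    end without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
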