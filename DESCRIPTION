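Package: drivermon
Title: Non-Contact Driver Vital-Sign Monitoring and e-Call Alerting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and decision toolkit for non-intrusive,
    in-cabin monitoring of a driver's physiological state. Provides a
    synthetic-data module that emulates capacitively coupled ECG (with a
    clothing-layer LC channel model and vehicle noise), state-dependent
    alpha/beta EEG mixtures, dual-wavelength photoplethysmography and 8x8
    thermal-array frames; signal conditioning (notch, Butterworth band-pass,
    moving average, stationary Haar wavelet denoising); an explicit Welch
    power-spectral-density estimator with alpha/beta band-power drowsiness
    scoring; Pan-Tompkins-style R-peak detection and heart-rate banding;
    ratio-of-ratios SpO2 estimation against a calibration table; thermal-grid
    overheat and flame classification; a five-phase alert state machine with
    ring-buffered pre-impact history and e-Call payload assembly; and an
    RBF-feature cognitive-state classifier. Includes CSV/JSON/JSONL dialects
    and an end-to-end monitoring pipeline over named synthetic scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
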