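Package: pulsebp
Title: Pulse-Waveform Analysis and Gaussian-Process Blood-Pressure Estimation
    Across Smoking Phases
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the acute effect of smoking on blood pressure
    from photoplethysmogram (PPG) and single-lead electrocardiogram (ECG)
    recordings: synthetic two-channel signal generation with exact fiducial
    ground truth and a known feature-to-pressure generative law, band-pass and
    mains-notch conditioning, fiducial detection (systolic peaks, pulse feet,
    dicrotic notches via the first derivative, R-waves), a 65-dimensional
    morphological and statistical window feature set, cubic-spline cohort
    expansion, principal-component reduction, and Gaussian-process regression
    of systolic and diastolic pressure with exponential and Matern-5/2
    kernels, including grid-search length-scale tuning with fivefold
    cross-validation and phase-wise summary reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
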