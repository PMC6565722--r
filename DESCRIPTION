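Package: ppgbp
Title: Calibration-Free Blood Pressure Estimation from Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A beat-level pipeline for cuffless blood-pressure estimation
    from single-channel finger photoplethysmography (PPG) sampled at 50 Hz.
    Detects pulse feet, systolic peaks and dicrotic notches; computes the
    second-derivative photoplethysmogram (SDPTG) and its a-e systolic waves;
    applies beat- and measurement-level quality control (robust outlier
    flagging, an SDPTG diastolic-segment noise test, 20 percent abnormal and
    30-cycle rules); extracts a 19-element feature vector (SVD waveform-shape
    coefficients, heart rate, Takazawa amplitude ratios b/a, c/a, d/a, e/a,
    stiffness index and body-mass index); trains perturbed-target bagged
    regression trees for systolic and diastolic pressure; validates with
    leave-one-subject-out cross-validation; and supports median-error personal
    calibration, Bland-Altman agreement analysis and age/pressure/perfusion
    stratified reporting. A seeded synthetic cohort generator produces 50 Hz
    waveforms with known morphology-to-pressure coupling so every stage is
    testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
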