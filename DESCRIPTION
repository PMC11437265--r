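Package: vitalband
Title: Pulse and Respiratory Rate Estimation from Neck-Worn PPG and
    Accelerometer Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed spectral estimation of pulse rate (BPM) and
    respiratory rate (BrPM) from dual-channel photoplethysmography and
    triaxial accelerometer recordings. Raw 30-second sliding windows are
    filtered, fused across channels and scored by a recursive,
    artifact-aware spectral dominance procedure; per-rate scores are
    smoothed by an exponentially weighted moving average tracker that
    emits interval ("rate band") estimates with confidence gating, and
    optionally a point rate value. Includes band-aware agreement
    statistics (RMSE, MAE, output percentage, Bland-Altman limits of
    agreement with components-of-variance for repeated measures) and a
    synthetic signal simulator with known rate schedules and
    controllable artifacts for end-to-end verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
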