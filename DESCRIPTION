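Package: pulsebp
Title: Cuffless Blood Pressure Estimation from Radial Pulse Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating systolic and diastolic blood pressure from
    multi-channel radial pulse waveforms measured by a tactile sensor array.
    Implements the full analysis pipeline: simulation of multi-channel pulse
    recordings with known ground truth, Hilbert-Huang (empirical mode
    decomposition) denoising with selective intrinsic-mode-function
    reconstruction, best-channel selection, per-beat fiducial-point detection
    and extraction of eleven waveform features, ensemble regression (random
    forest, gradient boosting, adaptive boosting) onto cuff-referenced blood
    pressure, and agreement evaluation via the coefficient of determination,
    Bland-Altman limits of agreement, and error-band accuracy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    xgboost,
    rpart,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
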