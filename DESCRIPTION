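Package: gazerp
Title: Co-Registered Eye-Tracking and EEG Analysis of Overt and Covert
    Attention Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for fixation-shift experiments that combine
    remote eye tracking (60 Hz gaze stream) with high-density EEG (128
    channels, 250 Hz). Provides gaze-trace repair and velocity-based
    saccade-onset detection, behavioral trial classification with
    exclusion rules, zero-phase Butterworth conditioning of continuous
    EEG, robust MAD-based epoch and channel screening, spherical-spline
    interpolation of bad channels, gaze-contingent gating of epochs
    contaminated by early saccades, electrode-cluster ERP peak measures,
    and condition summaries with effect sizes. Includes a synthetic
    session generator with ground-truth logging so the full pipeline can
    be exercised and validated without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
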