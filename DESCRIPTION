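Package: fogwatch
Title: Freezing-of-Gait Detection from Single-Wrist Inertial Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects freezing-of-gait (FoG) episodes in Parkinson's disease
    from a single wrist-worn inertial measurement unit (tri-axial
    accelerometer plus tri-axial gyroscope, 128 Hz). Continuous recordings
    are normalized against cohort-wide per-channel maxima, segmented into
    3-second sliding windows advanced every 0.25 s, and labeled FoG, Stop,
    or Walking-with-turns from clinician-style interval annotations. A
    compact one-dimensional convolutional network trained with Adam and
    early stopping classifies each window; classical baselines (decision
    tree and gradient boosting on time- and frequency-domain wrist
    features, including the freeze index) are provided for comparison.
    Evaluation supports shuffled 10-fold and leave-one-subject-out
    cross-validation with FoG-class sensitivity, specificity and F-score.
    A calibrated synthetic wrist-IMU cohort generator emulates published
    FoG episode-duration statistics so the full pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    rpart,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
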