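Package: stridefatigue
Title: Stride-Level Fatigue Analysis of Trunk-Mounted IMU Running Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting running-induced fatigue from
    lumbar-mounted inertial measurement unit (IMU) recordings. Provides a
    seeded synthetic gait-cohort generator with known ground-truth fatigue
    effects; zero-phase Butterworth preprocessing, foot-strike detection and
    time-normalized stride segmentation; per-stride time-domain, spectral and
    sample-entropy features; random-intercept mixed-effects models with
    standardized effect sizes (Cohen's d, marginal/conditional and partial
    R-squared); population-level classifiers evaluated with strict
    leave-one-participant-out cross-validation; personalized supervised and
    non-fatigued-baseline one-class anomaly detectors; and stride-to-stride
    variability and trajectory-complexity reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    randomForest,
    e1071,
    xgboost,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
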