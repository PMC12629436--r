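Package: gazerisk
Title: Collision-Risk Modelling from Gaze Entropy and Pupillometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the probability of a collision during transitions of
    control from automated driving using entropy-based gaze features
    (stationary and transition entropy of the fixation scanpath) and mean
    pupil diameter. Implements the full analysis pipeline: pupillometry
    preprocessing (blink interpolation, zero-phase Butterworth smoothing),
    gaze-entropy computation over spatial bins, class-imbalance correction
    of rare collision outcomes (SMOTE, random under- and over-sampling),
    standard and adaptive-LASSO penalized logistic regression with
    cross-validated penalty selection, cluster-robust covariance for
    repeated-measures designs, and an evaluation harness reporting
    classification accuracy at a fixed risk threshold, K-fold
    cross-validation error, ROC AUC, and calibration intercepts. A
    synthetic-data generator with known feature-to-risk structure supports
    simulation studies of how imbalance correction affects calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    glmnet,
    pROC
Config/testthat/edition: 3
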