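Package: gaitphase
Title: Gait Phase Recognition from Inertial Sensor Time Series with a ConvLSTM
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for frame-level human gait phase recognition from
    multi-channel inertial measurement unit (IMU) recordings. Provides a
    synthetic walking-data generator with known ground-truth phase
    boundaries, pressure-curve based five-phase label generation (initial
    contact, loading response, mid stance, terminal stance, swing), sliding
    window construction with sequence chunking and leave-one-subject-out
    splits, a convolutional-recurrent (ConvLSTM) classifier implemented from
    first principles with an Adam optimizer, and an evaluation suite
    covering confusion matrices, transition-tolerant accuracy,
    misprediction time offsets, softmax-certainty rejection and
    leave-one-subject-out cross-validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
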