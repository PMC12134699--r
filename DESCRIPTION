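Package: crswear
Title: Confounding-Resilient Smoking Gesture Detection from Wrist-Worn IMU Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting cigarette-smoking gestures from wrist-worn
    inertial sensors (3-axis accelerometer + 3-axis gyroscope) while remaining
    robust to confounding hand-to-mouth gestures such as eating, drinking and
    yawning. Provides a synthetic gesture simulator emulating a 16-activity,
    3-posture collection protocol; a recursive low-pass gravity filter that
    separates linear acceleration from the gravity component; a convolutional
    neural network classifier over 200-by-6 sensor windows, implemented with
    native code; a streaming detector with a notification cooldown and a
    simulated handshake/heartbeat device link; and an evaluation battery with
    confusion matrices, ROC/AUC by the trapezoidal rule, precision/recall/F1,
    stratified 60/20/20 splits and leave-one-subject-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Classification, TimeCourse, Software
RoxygenNote: 7.3.3
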