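Package: emgfuse
Title: User-Independent Hand-Gesture Recognition from EMG and IMU Sensor Fusion
Version: 0.1.0
Authors@R: person("emgfuse", "developers", role = c("aut", "cre"),
    email = "emgfuse@example.org")
Description: A tested pipeline for user-independent classification of hand
    gestures from an eight-channel surface electromyography (EMG) armband and
    a six-axis inertial measurement unit (IMU). Provides Butterworth/notch
    signal conditioning, Teager-Kaiser energy-operator (TKEO) double-threshold
    detection of muscle-activity onset and offset, sliding-window time-domain
    feature extraction with EMG+IMU feature-level fusion, and three
    subject-independent classifiers: an adaptive least-squares support vector
    machine with projected-subgradient transfer weights, a bilinear
    style/content factorization feeding a small neural network, and a classic
    multilayer perceptron trained on standardized labels. A seeded synthetic
    multi-subject cohort generator supplies data with the statistical
    structure the pipeline assumes, including planted ground truth for
    oracle tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
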