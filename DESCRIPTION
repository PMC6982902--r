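Package: motionteach
Title: Adaptive Vibrotactile Teaching of Periodic Human Motions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and testing adaptive motor-learning systems
    driven by wearable inertial sensors and vibrotactile actuator bands.
    Implements the full signal chain: quaternion-based frame transformation
    and gravity removal for MEMS accelerometer streams, first-order IIR
    low-pass filtering and drift-bounded integration, one-period pattern
    extraction from periodic motion signals, a translation- and
    scale-invariant pattern distance minimized by a two-stage coarse-to-fine
    grid search, kNNModel classification of multi-dimensional motion
    signals, phase synchronization via time patterns, motion-error and
    actuator-vector computation, two classification-dispatched teaching
    algorithms, and learning-efficiency statistics (RMSE-based E1/E2/E3
    scores with Shapiro-Wilk, Levene and Student's t analysis). A seeded
    virtual-learner simulator generates realistic periodic hand-trajectory
    sensor streams so that the whole loop can be exercised without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
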