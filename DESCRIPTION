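Package: canekin
Title: Cane Kinematics from Inertial Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Real-time kinematics estimation for an instrumented walking cane
    from 9-axis inertial measurement unit (IMU) data. Estimates the cane
    ground-contact phase per sample by a threshold rule on acceleration and
    angular-rate norms, by gyroscope gait-event detection (end contact,
    mid-swing, initial contact), and by a small 1D convolutional neural
    network with a causal majority-voting smoother. Estimates 3D cane
    orientation as unit quaternions by an accelerometer+magnetometer closed
    form, a Madgwick gradient-descent filter, and an error-state (indirect)
    Kalman filter that exploits the planted cane tip as a zero-velocity pivot
    during ground contact. Includes an analytic inverted-pendulum cane-gait
    simulator producing ground-truth orientation, phase labels and tip force,
    plus evaluation utilities (sample-wise phase accuracy, per-axis
    orientation RMSE, leave-one-subject-out cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
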