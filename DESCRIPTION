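Package: babyimu
Title: Gravity-Referenced Limb Orientation and Variability Metrics from
    Infant-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates infant limb orientation from ankle-worn inertial
    measurement units (tri-axial accelerometer, gyroscope, magnetometer)
    sampled at low rates such as 20 Hz. Isolates the gravitational component
    of acceleration with a zero-phase Butterworth filter, estimates and
    removes constant gyroscope bias from quiescent periods, and computes
    pitch, roll and yaw either from the gravity vector alone (pitch/roll;
    yaw is unobservable without a magnetometer) or by Madgwick-style
    gradient-descent sensor fusion.  Derives a composite scalar angular
    velocity in full-3D and accelerometer-only modes, summarises orientation
    variability with axis-specific circular standard deviations and the
    generalized variance (determinant of the circular covariance matrix of
    pitch, roll and yaw), and fits longitudinal linear mixed-effects models
    of age-related change plus rank correlations with standardized gross
    motor scores.  Includes a synthetic-data generator that renders IMU
    recordings from known ground-truth orientation trajectories and
    simulates longitudinal cohorts, so the whole pipeline is testable
    without access to recorded infant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmerTest,
    signal,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
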