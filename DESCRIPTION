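Package: gaitval
Title: Validation Toolkit for Wearable-Sensor Gait Analysis Against an
    Optoelectronic Criterion
Version: 0.1.0
Authors@R:
    person("gaitval", "developers", email = "gaitval@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative gait analysis with body-worn inertial
    sensors and a pocket smartphone, validated against marker-based motion
    capture. Implements uniform and quaternion time-series containers with
    linear and spherical-linear resampling, zero-phase Butterworth low-pass
    filtering, Madgwick gradient-descent orientation estimation, a
    configurable rigid-segment kinematic chain with marker- and
    orientation-driven inverse kinematics and Cardan angle extraction,
    kinematic gait-event detection (four marker-based procedures with a
    consensus combiner, and a peak/nadir detector for thigh-pocket vertical
    acceleration), per-cycle spatiotemporal parameters including a
    stride-length regression for phone data, and a complete
    method-agreement suite (Bland-Altman with confidence intervals,
    D'Agostino-Pearson normality, Welch tests against pooled reference
    distributions, mean absolute error, and the Linear Fit Method for
    waveform similarity). A ground-truth gait simulator generates coherent
    marker, inertial and phone recordings with known events so every
    pipeline stage is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
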