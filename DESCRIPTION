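Package: gaitmff
Title: Walking Trajectory Estimation by Mode-Finding Sensor Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the trajectory of a walking person by fusing GPS-like
    position fixes and IMU-derived dead-reckoned steps with a probabilistic,
    kinematics-driven step model. The posterior location belief at each step
    is non-Gaussian in Cartesian coordinates because the step model is
    Gaussian in polar step coordinates; the package condenses this belief to
    its mode with a gradient-ascent mode-finding filter (MFF) and provides a
    sequential importance resampling particle filter as a baseline. A
    scenario simulator generates ground-truth walks from a gait kinematic
    model and synthesizes per-step IMU and GPS measurement streams, and an
    evaluation layer runs Monte Carlo sensor/filter sweeps with RMSE
    reporting, profiling and CSV/GPX/JSON export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
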