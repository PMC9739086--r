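Package: wristkin
Title: Wrist-Worn IMU Kinematics for Throwing Sports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for wrist-worn 9-DoF inertial captures:
    quaternion algebra, Madgwick gradient-descent orientation fusion with a
    stabilization warm-up, gravity suppression and rotation into the
    north-east-down earth frame, moving-average smoothing, rectangle-rule
    integration, DC (drift) removal, zero-velocity updates, and instantaneous
    speed and 3D position reconstruction. Includes per-axis offset/slope
    calibration, a fixed-width 20-byte telemetry frame codec for low-energy
    radio links, a seeded synthetic IMU generator with a discus-throw preset
    so the whole pipeline is verifiable without hardware, and plotting of the
    reconstructed trajectory (3D, top view, side view) and speed profile.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
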