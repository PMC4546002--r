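Package: okndrive
Title: Optokinetic Nystagmus Analysis of Gaze Strategies in Curve Driving
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying where drivers look when steering through
    bends. Provides closed-form visual geometry of constant-radius
    cornering (tangent-point direction, waypoint lines of sight and their
    half-yaw-rate rotation law), a seeded simulator of multirate
    gaze/vehicle sensor records under tangent-point and future-path gaze
    strategies, optimal piecewise-linear segmentation of noisy gaze traces
    into optokinetic-nystagmus slow phases and saccades by dynamic
    programming, and the fixation-by-fixation comparison of slow-phase
    horizontal velocity against half the vehicle yaw rate, with
    per-subject aggregation, confidence intervals and condition contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
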