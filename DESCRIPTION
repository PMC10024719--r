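Package: codseg
Title: Segmentation and Timing of the Agility T-Test from a Trunk-Worn
    GNSS-IMU Sensor
Version: 0.1.0
Authors@R:
    person("codseg", "maintainers", email = "codseg@example.org",
           role = c("aut", "cre"))
Description: Detects the four change-of-direction (COD) events and five
    displacement phases of the Agility T-test from antero-posterior trunk
    acceleration recorded by a single trunk-worn inertial unit, and
    estimates total completion time by integrating GNSS ground speed over
    the final backward sprint. Provides zero-phase Butterworth filtering,
    stationary-wavelet band-limited signal reconstruction, adaptive
    threshold (quarter-mean-peak) minima detection, acceleration-impulse
    ranking of candidate COD segments, micro-adjustment rules for 90 and
    180 degree turns, Bland-Altman agreement statistics against
    video-resolution reference labels, and a synthetic trial simulator so
    the full pipeline is testable without athlete data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
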