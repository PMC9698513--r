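Package: arusim
Title: Marker-Based Tracking Engine for Monitor-Based Ultrasound Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for low-cost, monitor-based augmented-reality
    ultrasound training. Implements square binary fiducial (ArUco-style) marker
    dictionaries, marker detection in camera frames (adaptive thresholding,
    quad extraction, perspective removal, dictionary matching), 6-DoF marker
    pose estimation by reprojection-error minimisation, calibration between a
    body-tracking coordinate frame and the marker-tracking frame from four
    registered joints, and proximity/angle-driven selection of pre-recorded
    ultrasound frames from a gridded acquisition atlas. A synthetic-scene,
    synthetic-keypoint and synthetic-atlas generator replaces the webcam, the
    deep body-pose network and the real ultrasound recordings so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
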