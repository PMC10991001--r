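Package: gazeval
Title: Data Quality Validation for Wearable Eye Trackers Using a Fiducial-Marker Poster
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates accuracy, precision (RMS sample-to-sample and standard
    deviation), data loss and gaze range for wearable eye-tracker recordings in
    which a participant fixates targets on a printed poster carrying an array of
    fiducial (ArUco) markers of known geometry. Gaze reported in scene-video
    pixels is mapped to the poster plane through per-frame homographies
    estimated from detected marker corners; the viewing position is either
    assumed (fixed perpendicular distance) or continuously recovered by planar
    pose estimation when a scene-camera calibration is available. Includes an
    I2MC-style fixation classifier, nearest-fixation target matching with a
    minimum-duration rule, a synthetic-recording simulator with known ground
    truth, and a project workflow (import, annotate, process, export).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
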