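Package: gaitway
Title: Markerless Spatiotemporal Gait Analysis from 2D Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An engine for markerless gait analysis downstream of 2D pose
    estimation. Transforms 25-joint keypoint video streams (nominally 60
    fps) through screen, camera-normalized and depth-scaled world coordinate
    systems, applies distance-adaptive Savitzky-Golay smoothing, detects
    gait events (heel strike, toe off, heel rise, feet adjacent, tibia
    vertical) and stance/swing phases, and computes spatiotemporal gait
    metrics (gait speed, stride and step length, cadence, base of support,
    reaction and ignition times) over a standardized virtual walkway
    anchored by augmented-reality markers. Includes a parameterized
    articulated-walker simulator that provides analytic ground truth for
    every pipeline stage, and a method-comparison harness
    (Pearson/Spearman correlation, percent error, Bland-Altman limits of
    agreement) for validating recovered metrics against reference
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
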