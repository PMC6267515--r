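Package: stereogaze
Title: Stereoscopic Model-Based Gaze Reconstruction and Validation Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline gaze reconstruction for a head-free stereoscopic
    (two-camera, two-illuminator) video eye tracker. Triangulates the
    virtual pupil and the center of corneal curvature from per-frame pixel
    features, applies a one-point calibration (visual-axis offsets and the
    participant-specific corneal-center-to-pupil distance K), intersects
    the visual axis with the stimulus screen to obtain the point of gaze,
    and corrects systematic gaze errors with a variable gain that tracks
    the measured K. Includes a forward ray-tracing eye and rig simulator
    (spherical cornea acting as a convex mirror for glints, optional Snell
    refraction for the virtual pupil) used as the oracle for round-trip
    parameter-recovery tests, raster segmentation of synthetic eye images
    (threshold segmentation, least-squares ellipse fit, glint centroids),
    mirror-based system calibration of hidden illuminators and screen pose,
    and fixation and saccade validation analytics (accuracy, sample-to-sample
    precision, velocity-threshold saccade detection, main-sequence fits,
    Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    minpack.lm,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
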