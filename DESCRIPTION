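Package: kinovalid
Title: Validation of Markerless Joint-Angle Estimation Against Optical
    Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for validating joint angles estimated from tracked 3D
    body landmarks (RGB-D or monocular-RGB skeleton streams) against a
    high-rate marker-based optical motion-capture reference. Implements
    pinhole depth back-projection of 2D landmarks, ISB-style body
    coordinate systems and in-plane joint angles with an out-of-plane
    tolerance, dual-rate signal conditioning (zero-phase Butterworth and
    moving-average filtering), peak-based segmentation, quadratic
    resampling and synchronization, and agreement statistics (absolute
    error, RMS, clinical-reference error classification, Pearson
    correlation banding, Friedman and Wilcoxon rank tests). A synthetic
    motion generator produces ground-truth trajectories, forward-kinematics
    skeletons and noisy dual-rate virtual-camera streams so the whole
    pipeline can be exercised end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
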