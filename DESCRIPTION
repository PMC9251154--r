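Package: stereomark
Title: Fiducial Mark-Point Localization and Stereotactic Targeting in MR Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for locating circular and linear fiducial mark points in
    magnetic-resonance image slices and volumes and for registering them to a
    stereotactic frame. Provides a synthetic phantom generator with known
    ground truth, wavelet shrinkage denoising with a signal-to-noise metric,
    Canny-style edge detection, Hough-transform line and circle detection with
    a three-dimensional (a, b, r) accumulator and sub-pixel centre refinement,
    anchor- and collinearity-based mark-point matching against a frame
    template, SVD-based rigid registration with fiducial and target
    registration error reports, AC-PC coordinate construction with surgical
    target protocol checks, and pre/post UPDRS outcome statistics
    (improvement rate, efficacy tabulation, chi-square and paired t tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    jsonlite,
    yaml,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
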