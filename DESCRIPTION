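Package: gaitfuse
Title: Dual-Channel Gait Assessment from Smartphone Accelerometry and Video Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a reproducible pipeline for quantifying gait in older
    adults from two accessible data channels: tri-axial waist-worn smartphone
    accelerometer recordings, from which step frequency, acceleration RMS,
    step variability, and autocorrelation-based step regularity and symmetry
    are derived, and markerless video pose estimates in the OpenPose BODY_25
    keypoint format, from which sagittal joint angles, head and trunk posture
    angles, and spatiotemporal parameters (step length, cadence, speed, heel
    height) are derived after Daubechies-4 wavelet denoising. A synthetic
    cohort generator with controllable cadence, regularity, asymmetry, head
    pitch, and keypoint dropout produces both data streams with known ground
    truth, enabling end-to-end validation and calibrated group comparisons
    (Mann-Whitney U) between control and small-vessel-disease-like gait.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
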