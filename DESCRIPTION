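Package: pendknee
Title: Pendulum-Test Analysis of Knee Spasticity from Pose-Estimation
    Keypoints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Converts markerless pose-estimation keypoint trajectories
    (COCO 17-landmark convention, 2D or 3D) into sagittal knee flexion
    angle time series, extracts the pendulum-test swing landmarks and the
    clinical parameters P1 (normalized relaxation index), P2 (first
    maximum of oscillation) and P3 (relaxation index at half swing), and
    runs the method-agreement statistics used to validate video-based
    spasticity assessment against electronic goniometry: Bland-Altman
    limits of agreement with proportional-bias regression, two-way
    random-effects consistency ICC, paired limb comparison with effect
    sizes, and Spearman correlation with Modified Ashworth Scale scores
    after interquartile-range outlier screening. A damped-oscillator
    simulator generates multi-subject synthetic pendulum-test cohorts
    (goniometer traces plus rendered noisy 2D/3D keypoint files) with
    closed-form ground truth, so the full pipeline is verifiable end to
    end without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
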