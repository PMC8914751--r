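Package: gaitless
Title: Markerless 3D Gait Analysis from Multi-View Keypoint Trajectories
Version: 0.1.0
Authors@R:
    person("Open", "Biomechanics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for video-based markerless gait analysis downstream of a
    2D pose detector: pinhole camera models and multi-view DLT triangulation
    of keypoints into 3D trajectories, zero-phase Butterworth filtering and
    gap interpolation, heel-strike and toe-off detection from foot-keypoint
    speed, spatio-temporal gait parameters (stride length and time, stance
    and swing percentages, step width, speed), geometric joint-angle curves
    over the normalized gait cycle, pose-estimation accuracy metrics (PCKh
    and MPJPE), and scalar plus one-dimensional statistical parametric
    mapping paired t-tests for comparing marker-based and markerless
    measurement systems. Includes a kinematic walking simulator with exact
    ground-truth events, parameters and angle profiles, a virtual multi-view
    camera rig, CSV/JSON readers and writers, and a TRC exporter for
    OpenSim interoperability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
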