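Package: skitrax
Title: Markerless Cross-Country Skiing Kinematics and Sub-Technique Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning per-frame human key-point trajectories from
    markerless video pose estimation into cross-country skiing sub-technique
    labels. Provides a skeleton schema and pose-sequence container with CSV
    and JSON input/output, reference implementations of anchor-box decoding,
    multi-task detection losses, non-maximum suppression and keypoint-to-person
    fusion, 3D lifting loss functions, trajectory gap filling and joint-angle
    computation, EM and zero-phase Butterworth trajectory smoothing, motion-cycle
    segmentation from ankle and pole-tip trajectories, time- and frequency-domain
    waveform descriptors with support vector machine classification of double
    poling, diagonal striding and downhill tuck, pose-estimation evaluation
    metrics (PCK, MPJPE, MAEA), and a parametric simulator of 3D skiing
    kinematics with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
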