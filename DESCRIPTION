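Package: gaitacf
Title: Video-Free Gait Quantification from 2D Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts 2D body-keypoint time series from a markerless pose
    estimator into gait feature signals (inter-leg angle and bilateral
    leg-length-ratio difference), estimates cadence by short-time
    autocorrelation pitch detection with a second-positive-phase peak rule,
    and scores step periodicity of pathological (freezing-of-gait) sequences
    by dynamic-time-warping and k-nearest-neighbour distances from a
    normal-gait autocorrelation reference. Includes a synthetic gait
    generator with known ground-truth cadence, freezing episodes and
    detection dropouts, plus a command-line pipeline.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    pROC,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
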