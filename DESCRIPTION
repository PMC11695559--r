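Package: gaitheel
Title: Marker-Less Heel Keypoint Detection and Step Parameters from Gait Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-step marker-less pipeline for video-based gait analysis.
    Coarse whole-body pose trajectories (25-keypoint BODY_25 JSON) locate
    heel-strike events and foot regions; compact convolutional keypoint
    networks (VGG19, ResNeXt50 or MobileNetV2 backbone with a coordinate
    regression or heatmap head) refine the heel contact point in fixed-size
    160x120 foot crops; a floor-plane homography estimated from marked floor
    points projects image predictions to world coordinates, from which step
    length, step width and floor-axis error statistics are computed.
    Includes a synthetic-data generator (foot silhouettes with known heel
    ground truth, gait-like trajectories with planted heel strikes,
    calibration scenes) so the whole pipeline is testable without clinical
    recordings, and a self-contained CNN engine (Rcpp) for training the
    keypoint networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, png, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
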