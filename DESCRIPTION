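Package: poselink
Title: Multi-Animal Pose Assembly, Tracking and Tracklet Stitching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bottom-up multi-animal pose processing: decoding of score maps,
    location refinement fields and part affinity fields (PAFs) into keypoint
    detections and limb affinity costs; data-driven selection of the part
    affinity graph (skeleton) by auROC ranking and maximum spanning trees;
    grouping of detections into individual animals via optimal pairing,
    connected components, greedy linking and an optional Mahalanobis pose
    prior gate; local tracking-by-detection with Kalman-filtered box and
    ellipse trackers; globally optimal tracklet stitching by min-cost
    network flow over motion, proximity, shape, dynamics and appearance
    affinities; and the standard evaluation suite (RMSE, PCK, OKS-mAP,
    assembly purity, CLEAR-MOT). A deterministic synthetic multi-animal
    scene generator renders ground-truth target tensors so the whole
    pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    igraph,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
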