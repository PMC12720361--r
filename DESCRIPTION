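Package: thermomap
Title: Cross-Modal RGB-Infrared Mapping for Region-Based Animal Thermometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for region-of-interest thermometry with dual-channel
    (visible + thermal infrared) cameras. Calibrates an RGB-IR rig from
    checkerboard corner observations (Zhang's method), maps semantic
    segmentation masks of chicken head regions (comb, eye, beak, wattle)
    from the RGB frame into the infrared frame via a per-point cross-modal
    coordinate mapping chain (undistortion, normalization, planar depth
    back-projection, rigid extrinsic transform, re-projection), extracts
    per-region temperature statistics from infrared temperature matrices,
    quantifies the mapping's sensitivity to depth error, and evaluates
    segmentations with confusion-matrix metrics (per-class IoU, MIoU, MPA)
    and class-imbalance-aware losses (focal, dice). Includes a seeded
    synthetic-scene generator (rigs, checkerboard observations, head-region
    masks, temperature fields) used as the test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
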