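Package: spinetrack
Title: Dendritic Spine Detection, 3D Tracking and Evaluation for Two-Photon
    Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for automated dendritic spine detection in 3D two-photon
    fluorescence image stacks: per-slice detection post-processing
    (confidence, area and duplicate filtering), a z-axis tracking algorithm
    that assembles per-slice bounding boxes into 3D spine tracks, overlap
    metrics based on the Intersection over Minimum (IoM) in the image plane
    and along depth, F1-style evaluation in 2D and 3D, fusion of multiple
    annotators' labels into minimal/majority/maximal consensus ground
    truths, anchor-grid geometry and label assignment for region-proposal
    detectors, a classical reference detector, and a synthetic stack
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
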