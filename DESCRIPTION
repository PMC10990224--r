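Package: skyfilter
Title: Filtering, Detection and Evaluation for Aerial Marine-Bird Survey Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage processing workflow for high-resolution aerial
    imagery of open water collected during marine-bird surveys. Stage one
    filters frames by the probability that they contain at least one bird,
    stage two detects individual birds with a classical blob-proposal +
    HOG + linear-SVM detector, and a bootstrap annotation-refinement step
    tightens loose bounding boxes using an activation map and a two-phase
    morphological level set. Includes a sliding-window tiler with
    non-maximum suppression for cross-patch merging, COCO-style
    mAP/AR evaluation stratified by ground sample distance, and a
    synthetic open-water scene generator with exact ground truth so the
    whole pipeline is testable without survey imagery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    glmnet,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
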