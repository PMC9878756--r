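Package: ettassess
Title: Automated Assessment of Endotracheal Tube Placement on Chest
    Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-detection computational pipeline for automated reading of
    endotracheal tube (ETT) placement on intensive-care chest radiographs.
    Converts landmark detections (ETT tip and carina bounding boxes with
    confidence scores) into a calibrated ETT-carina distance with an
    exponential confidence-to-uncertainty model, applies an
    uncertainty-adjusted 2-cm placement rule with a coupled human/model
    reading, segments the tube by classical image processing (Hessian ridge
    detection, vertical filtering, morphological opening, decile
    binarization, DBSCAN clustering and an upward cluster-thinning walk),
    and computes the associated evaluation statistics (mean absolute error,
    compound-symmetry mixed-model mean error, rater agreement, sensitivity
    and specificity). A synthetic phantom radiograph generator with exact
    ground truth supports end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    nlme,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
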