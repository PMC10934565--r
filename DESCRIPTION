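Package: lungdiff
Title: Longitudinal Chest Radiograph Comparison: Segmentation, Registration,
    Difference Enhancement and Multi-Label Classification
Version: 0.1.0
Authors@R: person("lungdiff", "maintainers", email = "lungdiff@example.org",
    role = c("aut", "cre"))
Description: A four-stage toolkit for comparing pairs of chest radiographs of
    the same subject taken at different times. Provides classical lung-field
    segmentation (CLAHE, Otsu thresholding, connected components, morphology)
    and a small one-stage anchor-based lung-box detector; deformable
    registration by dense displacement-field gradient ascent or a learned
    U-Net registration network; post-image-weighted difference maps with
    sigmoid-style nonlinear enhancement and heat-map overlays; and single- and
    dual-input multi-label disease classifiers with a channel-weighting fusion
    block. A synthetic phantom generator supplies pre/post image pairs with
    ground-truth lung masks, boxes, dense deformation fields and lesion labels
    so that every stage can be exercised and tested without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
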