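Package: cystwise
Title: Cyst-Wise Evaluation of Segmentations of Engineered Polycystic Kidney Tubules
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An evaluation pipeline for cyst segmentation in RGB
    immunofluorescence images of engineered polycystic kidney tubules.
    Provides green-channel muting ("no-G") preprocessing and a joint
    image/mask augmentation pipeline, a pluggable segmentation backend
    contract with a compact trainable encoder-decoder reference network,
    flood-fill hole filling and circular-element opening/closing
    postprocessing, pixel-wise and cyst-wise (detected/missed/wrong)
    metrics with deterministic overlap matching, size-zone stratification
    of object-level performance, and leave-one-tubule-out (LOTO)
    cross-validation fold construction with tubule-level aggregation.
    A synthetic fluorescence scene generator with exact ground truth and
    a controlled mask perturber make every stage testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: CellBiology, Software, Segmentation, Visualization
RoxygenNote: 7.3.3
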