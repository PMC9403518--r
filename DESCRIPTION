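Package: crownscope
Title: Tree-Crown Extraction from UAV Visible Imagery with Elevation Layers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: End-to-end pipeline for individual tree-crown extraction from
    UAV-style visible orthomosaics augmented with elevation layers. Builds
    model-input rasters (excess green index, canopy height model derived from a
    digital surface model by minimum/mean filtering), trains a residual U-Net
    binary segmentation model on tiled band stacks, measures per-crown width,
    projection area and height from predicted masks via edge extraction and
    direct least-squares ellipse fitting, and evaluates detection (IoU-matched
    precision/recall/F1) and regression (R2, RMSE, rRMSE) accuracy. Ships a
    seeded synthetic-orchard scene generator so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
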