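Package: wheatsyn
Title: Synthetic Wheat Scenes and Heatmap-Supported Domain Adaptation for
    Wheat Head Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Procedural generation of synthetic wheat-field scenes with
    bounding-box and Gaussian-heatmap annotations (L-system stems, wind
    bending, pinhole-camera projection), an unpaired image translator in
    the CycleGAN family whose generators are regularised by lightweight
    UNet heatmap-regression support networks, appearance-based K-means
    partitioning of a heterogeneous target domain into multiple
    translation targets, assembly of the resulting training datasets, and
    a detection evaluation suite (mean intersection-over-union and mean
    centre Euclidean distance after confidence filtering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
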