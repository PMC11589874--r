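Package: plstree
Title: Individual Tree Point Clouds from Permanent Laser Scanning Scenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain that turns raw tilted permanent-laser-scanner
    (PLS) forest scenes into georeferenced, quality-flagged single-tree point
    clouds with per-tree metadata and a JSON catalogue. Covers LAS point-cloud
    input/output with extra-byte attributes, scene rectification and scan-angle
    derivation, seven-parameter Helmert georeferencing, voxel-based resampling
    with attribute averaging, stem detection by local PCA verticality and
    cylinder fitting, coarse cylinder-buffer segmentation, DTM height
    normalization, layer-by-layer fine segmentation (DBSCAN plus an iterative
    fuzzy k-nearest-neighbour sweep), per-tree attribute extraction and quality
    flagging, reusable validation metrics, and a seed-reproducible synthetic
    scene generator that emulates the acquisition geometry with per-point
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    data.table,
    jsonlite,
    yaml,
    minpack.lm,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
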