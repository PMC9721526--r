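Package: topofit
Title: Topology-Aware Image Segmentation with Persistent Homology Losses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Persistent homology of super-level-set cubical filtrations of 2D
    images and 3D volumes, a differentiable barcode loss that drives a
    segmentation probability map towards user-specified Betti numbers, and
    two training frameworks built on that loss: per-item post-processing
    adaptation of a trained network, and semi-supervised training in which
    unlabelled images contribute a purely topological gradient. Includes a
    compact U-net implementation for 2D and 3D with reproducible training, a
    synthetic-data generator (Fourier-domain line-removal corruption and
    phantoms of known topology), evaluation metrics, barcode plotting and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    RNifti,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
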