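Package: MicroEnvNet
Title: Voxel-Based Deep Learning Analysis of Protein Microenvironments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts backbone-oriented, side-chain-stripped 20 Angstrom local
    boxes around amino-acid sites in protein structures, voxelizes them into
    four atom-element channels (O, C, N, S) with Gaussian smoothing, and
    trains a 3D convolutional neural network to classify the 20 amino-acid
    microenvironment types. From the resulting prediction confusion
    statistics it derives two structure-based amino-acid substitution
    matrices (a symmetrized log-odds matrix and a profile dot-product
    matrix), builds cross-validated classifiers of mutation effects on
    protein stability from substitution-score features, and computes
    gradient-times-input atom importance maps exported as PDB B-factors.
    Includes a synthetic-structure generator with planted atom-arrangement
    patterns so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    bio3d,
    Biostrings,
    glmnet,
    e1071,
    pheatmap,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
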