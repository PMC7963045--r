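Package: jsomap
Title: Jointly Evolving Self-Organizing Maps for Aligning Paired Single-Cell Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Aligns two related single-cell datasets (possibly from different
    technologies with different feature panels) by training two coupled
    self-organizing-map grids that evolve jointly through a cross-dataset
    matching function built from shared features. Provides correlation- and
    binarization-based (step-fit) matching, density-dependent downsampling,
    post-training node assignment, Ward superposition clustering, mode maps
    and label transfer, plus alignment-quality metrics (node purity score,
    matching score, per-feature grid RMSE, average Kullback-Leibler
    batch-mixing divergence) and a synthetic paired-dataset generator for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
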