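Package: hmfw
Title: Hybrid Multiple Filter-Wrapper Feature Selection for High-Dimensional Omics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Feature selection and biomarker discovery for high-dimensional omics
    classification (microarray and proteome matrices with tens of samples and
    thousands of features). Implements a dual-module hybrid pipeline: random-forest
    impurity pre-screening; a bivariate filter combining maximum mutual information
    with the label and minimum Spearman redundancy among selected features, with
    iteration-dependent relevance/redundancy weights; a binary grey-wolf wrapper with
    median-threshold binarization and chaotic dung-beetle refinement around the three
    pack leaders, scored by cross-validated SVM (RBF) accuracy; and a process
    optimization controller that monitors the average improvement rate against a
    patience schedule derived from the extrema of a sum-of-sines intensity model,
    restarting the filter to escape local optima. Includes a seeded synthetic-data
    generator emulating the target data regime and tools for repeated runs, reports
    and planted-feature recovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    e1071,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
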