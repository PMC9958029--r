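Package: hnsccStepwise
Title: Stepwise Progression Analysis of Head and Neck Cancer from Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying the stepwise progression of head and
    neck squamous cell carcinoma (normal tissue, leukoplakia, primary carcinoma,
    nodal metastasis) from single-cell RNA-seq. Implements expression-based
    copy-number inference with circular binary segmentation and recurrence
    calling, detection of carcinoma-in-situ cells in premalignant lesions,
    permutation-based differential expression and stepwise-gene discovery,
    interdependent ligand-receptor analysis between fibroblasts and malignant
    cells, and signature-based bulk deconvolution with percentile survival
    stratification. Includes a synthetic cohort generator that plants known
    ground truth (clonal copy-number segments, a carcinoma-in-situ subclone,
    stepwise ligand programs, mixing proportions, proportion-linked survival)
    so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    survival
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
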