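Package: gonadscore
Title: Cell-Identity Scoring and Lineage Statistics for Fetal Gonad scRNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality-control filtering, normalisation and cell-cycle phase
    assignment for single-cell RNA-seq of the fetal mouse gonad, followed by
    machine-learning Sertoli (SCI) and granulosa (GCI) cell-identity scoring:
    ROC-AUC marker ranking, cross-validated stepwise logistic model building
    capped at 50 signature genes, per-cell scoring on a 0-100 scale,
    hyperbola-based double-positive cell classification, ICA projection with
    logistic-regression label transfer between strains, and cell-type
    proportion and score statistics (chi-square/Fisher with FDR, PCA of
    proportions, Wilcoxon comparisons). Includes a negative-binomial
    synthetic-data generator with planted marker programs so the whole
    pipeline runs against a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    nnet,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
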