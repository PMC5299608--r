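Package: mtcret
Title: Transcriptome Analysis of Medullary Thyroid Cancer by RET Mutation Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk expression profiling of medullary
    thyroid carcinoma (MTC) stratified by RET mutation status. Provides
    variability-based probe-set filtering of RMA-summarized microarray
    matrices, Ward hierarchical clustering of samples, per-probe Welch
    t-tests with Benjamini-Hochberg FDR control and linear fold changes,
    a leave-one-out cross-validated linear support-vector-machine
    classifier of RET mutation class with fold-internal univariate gene
    selection, and an RT-qPCR validation stage (standard-curve
    quantification, geNorm reference-gene stability and normalization,
    Mann-Whitney U tests with Bonferroni correction). A synthetic-data
    generator emulates the cohort structure of the study design so the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    e1071,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
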