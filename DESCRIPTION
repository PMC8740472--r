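Package: ctap
Title: Cohort-Based Transcription-Factor Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts consistently up- or down-regulated transcription-factor
    target genes by integrating many test-versus-control expression comparisons
    ("comparison pairs") drawn from heterogeneous studies. Comparisons are
    summarised as Laplacian-corrected log2 ratios, the assembled cohort matrix
    is normalised with trimmed quantile normalisation, and gene-regulation
    state is learned from functional-group marker genes using five features
    (log2 fold change plus four abundance Z-scores). Candidate targets from
    ChIP-derived lists are then called Up or Down under an error-tolerance
    consensus rule, with Gene-Present-Sufficiently / Gene-Absent-Insufficiently
    pattern annotation. Includes a seeded multi-study cohort simulator with
    planted ground-truth targets for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, e1071, glmnet, pROC
Suggests: testthat (>= 3.0.0), limma, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
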