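Package: lncsig
Title: Sparse SVM Gene Signatures for Tumor Subtype Classification and Prognosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects compact coding and long non-coding gene signatures that
    discriminate tumor intrinsic subtypes, using a recursive two-iteration
    1-Norm (L1-penalized, squared-hinge) support vector machine with
    one-vs-rest multiclass attribution. Includes GENCODE-style biotype and
    length filtering for long non-coding RNAs, per-gene max normalization,
    repeated stratified cross-validation with a 2-Norm SVM, t-SNE
    visualization, prediction of unlabeled samples with
    immunohistochemistry-marker concordance tables, a supervised principal
    components (superPC) survival model with Gaussian-mixture risk
    stratification, Kaplan-Meier/log-rank and Cox proportional-hazards
    summaries, and a synthetic cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    Rcpp,
    S4Vectors,
    data.table,
    jsonlite,
    mclust,
    pROC,
    Rtsne,
    rtracklayer,
    stats,
    survival,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    e1071,
    quadprog,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
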