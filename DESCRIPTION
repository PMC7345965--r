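Package: aastone
Title: Urinary Amino Acid Profiling of Kidney Stone Formers by
    Double Cross-Validated PLS-DA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to discover and validate a urinary amino acid
    fingerprint separating kidney stone formers from healthy controls.
    Implements partial least squares discriminant analysis (NIPALS PLS1
    on a binary-coded response) with repeated stratified double
    cross-validation for latent-variable selection and unbiased
    classification rates, biomarker selection by variable importance in
    projection (VIP) and rank product (RP) with consensus ranking, and
    permutation-based significance of the number of misclassifications
    (NMC), AUROC and discriminant Q2. Includes a moment-matched
    synthetic cohort generator parameterized from published group
    summary statistics, so the whole pipeline is reproducible without
    access to per-subject data, plus univariate group comparisons and
    CSV/JSON result export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics,
    pROC
biocViews: Metabolomics, Classification, Regression, StatisticalMethod
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'aastone-package.R'
    'cohort-spec.R'
    'cohort-table.R'
    'generate.R'
    'scaling.R'
    'plsda.R'
    'metrics.R'
    'dcv.R'
    'selection.R'
    'permutation.R'
    'univariate.R'
    'pipeline.R'
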