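Package: targetexpress
Title: Context-Specific Refinement of microRNA Target Predictions
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Refines sequence-based microRNA target predictions for a
    specific cellular context by combining prediction scores (TargetScan
    Total Context+ and PCT, microT-CDS miTG, and MIRZA canonical,
    target-frequency and non-canonical scores) with a single
    gene-expression profile, using an ensemble of class-weighted
    radial-kernel support vector machines.  One SVM is trained per
    eligible miRNA-perturbation experiment and their decision values are
    summed into a consensus score; positive consensus indicates a
    predicted functional target in the supplied expression context.
    Includes construction of True-Target/False-Target training labels
    from differential-expression tables, rank plus min-max feature
    scaling with neutral imputation of missing scores, 3'UTR windowing
    and log-sum aggregation of per-site scores, ROC/AUC evaluation with
    experiment-level leave-one-out cross-validation and paired Wilcoxon
    method comparison, hypergeometric seed-match enrichment quality
    control along ranked gene lists, rank-based gene-set tests, and a
    seeded generator of synthetic perturbation experiments for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    e1071,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    limma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
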