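Package: perturbsig
Title: Perturbation-Derived Gene Expression Signatures and Cohort Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a directional gene-expression signature from a small
    two-condition microarray perturbation experiment (detection filtering,
    generalized-log variance-stabilizing transformation, quantile
    normalization, empirical-Bayes moderated t-statistics, FDR and
    fold-change thresholding), characterizes it by hypergeometric gene-set
    enrichment and signature overlap, and projects it onto an independent
    cohort by Pearson correlation of each sample with the signature
    centroid, with per-subset score summaries, direction-concordance
    fractions and average-linkage sample clustering. Includes seeded
    simulators for both the perturbation experiment and the cohort so the
    whole pipeline is testable against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
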