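Package: pdacsig
Title: Prognostic Gene-Signature Derivation and Validation for Localized
    Pancreatic Cancer Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for deriving and validating prognostic
    gene-expression signatures from two-color microarray studies of
    pancreatic ductal adenocarcinoma. Implements lowess (MA) normalization,
    intensity-based gene filtering, k-nearest-neighbour imputation,
    distance-weighted discrimination (DWD) batch adjustment, two-class
    significance analysis of microarrays (SAM) with permutation-estimated
    false discovery rates, a nearest-centroid single-sample predictor
    using (1 - Pearson correlation) distance, optimal survival cut-point
    selection by maximally selected log-rank statistics, and downstream
    Kaplan-Meier, log-rank, Cox, and contingency-table validation
    statistics. Ships a synthetic-data generator that emulates the
    two-cohort, batch-shifted, matched tumor-normal study design the
    pipeline assumes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
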