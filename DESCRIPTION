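Package: ddpp
Title: Digital Display Precision Predictor for Transcriptomic Outcome Modeling
Version: 0.1.0
Authors@R:
    person("WIN", "Methods", email = "methods@example.org", role = c("aut", "cre"))
Description: Builds parameter-free transcriptomic predictors of
    progression-free survival (PFS) from paired tumor and organ-matched
    normal expression profiles. Per-gene features combine the log2
    tumor/normal fold change with the log base-1.1 intensity of a chosen
    channel; genes from a drug-specific literature panel are ranked by
    Pearson correlation with PFS, collapsed by step-in prefix subsets
    under five parameter-free vector summations (sum, mean, median,
    product, absolute product), and the best-performing subset and method
    are turned into a linear predictor of PFS in months. Includes
    leave-one-out validation, random-gene-set null scans, cross-drug
    specificity tests, whole-transcriptome discovery scans, packaged drug
    panels with published predictor equations, a synthetic-cohort
    generator with planted signatures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
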