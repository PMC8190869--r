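Package: methdmr
Title: Differentially Methylated Region Discovery and Liver-Metastasis
    Risk Modelling from Targeted Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for calling differentially methylated regions (DMRs)
    from per-CpG bisulfite sequencing counts in fixed 1000-bp windows,
    filtering them into prognostic marker sets (effect-size and FDR gates,
    Jonckheere-Terpstra stage-trend test, promoter overlap), and building
    an L1-penalized logistic regression model of liver-metastasis risk
    with leave-one-out cross-validation, ROC evaluation and Kaplan-Meier
    survival stratification. Includes a beta-binomial synthetic-cohort
    generator with planted differential and trend windows so the full
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
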