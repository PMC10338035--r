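Package: omicage
Title: Child Biological Age Clocks and Association Analysis from Multi-Omic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds candidate biological age clocks for school-age children from
    multi-omic feature blocks (plasma proteins, serum and urinary metabolites,
    transcripts) by elastic-net regression on chronological age, computes qPCR
    relative telomere length (T/S), derives delta age (predicted minus
    chronological age), and runs the covariate-adjusted association framework
    against developmental outcomes and health risk factors with
    Benjamini-Hochberg false discovery rate control. Includes assay-style
    preprocessing (limit-of-quantification filtering, plate-effect centering,
    truncated-normal imputation of censored values, median-fold-change
    normalization of urinary dilution), over-representation analysis of clock
    predictors against GMT gene-set collections, questionnaire and cognitive
    score derivations, and a synthetic-cohort generator with recorded ground
    truth so every stage is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, Metabolomics, Proteomics, Regression, BatchEffect
RoxygenNote: 7.3.3
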