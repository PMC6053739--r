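Package: stagepath
Title: Stage-Specific Co-Expression Networks and Pathway Deviation
    Scoring for Early Cancer Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A staged transcriptome biomarker pipeline for three-group
    (control / early / late) expression studies. From a genes-by-samples
    expression matrix it performs control-referenced z-score
    normalization, extracts phase-specific differentially expressed gene
    sets with a moderated t-statistic, builds and compares per-phase
    signed co-expression networks with standard topology metrics,
    converts network degree to gene weights through a sigmoid, scores
    pathway deviation with a permutation-calibrated maximum running-mean
    statistic, screens pathways by one-way ANOVA, and trains and
    evaluates an RFE+SVM diagnostic model. A synthetic-data module
    generates inputs with planted ground truth so every stage of the
    pipeline is verifiable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pROC,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
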