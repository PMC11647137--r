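Package: IKCscore
Title: Immune-Keratin-Checkpoint Scoring for Immunotherapy Response Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives and applies a composite transcriptomic biomarker of
    immune-checkpoint-blockade response from bulk tumor RNA-seq. Signature
    scores are computed with a single-sample gene-set enrichment (ssGSEA)
    running-sum statistic; response-associated signatures and genes are
    screened with rank-sum tests, clustered with K-means into immune and
    keratin expression patterns, and combined into a single score
    (Immune score + Immune Checkpoint score - Keratin score) that is
    evaluated with ROC/AUC, Kaplan-Meier, log-rank and Cox statistics.
    Includes a negative-binomial cohort simulator with planted immune and
    keratin programs and outcome-linked survival for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    DESeq2,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, ImmunoOncology, GeneSetEnrichment, Survival,
    Transcriptomics, Classification
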