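Package: methylGDM
Title: Integrated Methylation and Expression Association Analysis for
    Gestational Diabetes Placenta Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for integrated
    epigenome-wide and transcriptome-wide association analysis of
    gestational diabetes mellitus (GDM) in placental tissue. Provides
    450K-style intensity-to-beta conversion, quantile normalization,
    probe-type bias adjustment and probe filtering; quantile-baseline
    background correction and median-polish summarization of expression
    arrays; surrogate-variable estimation for batch and ethnicity
    confounding; per-CpG and per-gene linear models with
    heteroscedasticity-robust Wald tests; bump-hunting detection of
    differentially methylated regions; linear mixed models with effect
    modification for pyrosequenced regions; permutation-based Spearman
    correlation networks between methylation and expression within a
    genomic window; and gene-ontology enrichment with a resampling null
    that corrects the non-random probe design of methylation arrays.
    A synthetic cohort generator with a recorded ground-truth ledger
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    limma,
    sandwich,
    lme4,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: DNAMethylation, GeneExpression, Epigenetics, BatchEffect,
    DifferentialMethylation, GeneSetEnrichment
RoxygenNote: 7.3.3
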