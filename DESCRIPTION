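Package: oligomiR
Title: Locus Enrichment, Pathway Co-Targeting, Co-Repression and Survival
    Analysis for Clustered MicroRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Statistical toolkit for associating genomically clustered
    microRNAs (such as the 14q32/DLK1-DIO3 cluster) with an oligometastatic
    phenotype. Implements permutation and exact hypergeometric tests for
    genomic-locus enrichment of differential microRNA sets, per-microRNA
    pathway over-representation of predicted targets with Fisher's combined
    probability summaries, SAM-style permutation differential expression for
    transfection experiments with Venn and chi-squared co-repression
    statistics, Kaplan-Meier / log-rank survival stratification by mean
    microRNA expression, and a synthetic-data generator with planted ground
    truth for end-to-end validation of the whole chain.
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
    rtracklayer,
    limma,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'enrichment.R'
    'expression.R'
    'panel.R'
    'io.R'
    'synthetic.R'
    'pipeline.R'
    'survival.R'
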