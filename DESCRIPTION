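Package: methcapdm
Title: Differential Methylation Analysis for Methyl-Capture Bisulfite
    Sequencing Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for cord-blood DNA methylome studies based
    on targeted bisulfite (methyl-capture) sequencing: per-CpG read-count
    quality filtering (coverage bounds, minimum-sample retention, region
    exclusion), reference-based cord-blood cell-type deconvolution by
    nonnegative least squares, per-CpG binomial generalized linear model
    association testing with covariate adjustment and Storey q-value false
    discovery control, direction-aware merging of differentially methylated
    cytosines into regions, principal-component gap changepoint detection of
    global methylation outlier samples, imprinting-control-region methylation
    summaries with factorial analysis of variance, annotation enrichment
    tests, and cohort demographic comparisons. A seeded synthetic-cohort
    generator with planted effects, cell mixtures, imprinted blocks and
    outlier samples provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    pracma,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
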