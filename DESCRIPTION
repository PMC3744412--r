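Package: pooledQTL
Title: QTL Mapping from Pooled-Segregant Whole-Genome Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bulk segregant analysis (BSA-seq) of experimental crosses:
    quality filtering of parent-distinguishing SNP markers, penalised
    binomial spline smoothing of pooled SNP variant frequencies on the
    logit scale, Monte-Carlo simultaneous confidence bands and
    threshold-aware multiplicity-adjusted p-values for the log-odds
    contrast between phenotypically selected and unselected segregant
    pools, QTL region calling, and exact binomial fine-mapping statistics
    for individually genotyped segregants with Benjamini-Yekutieli FDR
    control. Includes a synthetic meiotic cross generator (Poisson
    crossovers, selectable pools, allele-specific epistasis and
    downgraded-parent crosses) so that every inferential stage can be
    validated by parameter recovery on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
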