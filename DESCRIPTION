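Package: cnvrkit
Title: CNV Detection from SNP Array Signals, CNVR Aggregation and
    Cross-Study Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for copy-number variant (CNV) analysis
    of Illumina-style SNP array data: marker- and sample-level quality
    control, a hidden Markov model that segments Log R Ratio / B Allele
    Frequency signals into copy-number states, aggregation of per-sample
    calls into copy-number-variable regions (CNVRs) with summary
    statistics, cross-study CNVR comparison (novelty classification,
    composite sets, ordination, breed-specific regions), feature-overlap
    annotation with gene-set enrichment, and qPCR copy-number validation
    arithmetic. A synthetic-data generator produces genomes, marker maps,
    ground-truth CNVs and signal matrices so the whole pipeline can be
    exercised and tested without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vegan,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
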