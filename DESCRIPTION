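Package: lenbias
Title: Gene-Length Capture Bias Between Single-Cell and Single-Nucleus
    RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the gene-length and exon-count capture bias between
    single-cell and single-nucleus RNA sequencing. Provides a seeded
    simulator of paired count matrices with a planted, parameterized
    length-dependent capture efficiency; quality-control filtering and
    log-normalization; depth-matched balanced cell subsampling; Wilcoxon
    rank-sum and negative-binomial GLM differential expression with
    marker-list filters; structural annotation of gene lists (exon count,
    transcript and CDS length, genomic span) with skewness and
    genome-background comparisons; per-cell single-sample gene-set
    enrichment scoring; and a one-call pipeline that runs the whole
    analysis from a config and emits a machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
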