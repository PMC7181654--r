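Package: lncTempo
Title: Biotype-Resolved Temporal Transcriptome Analysis of Neuronal
    Differentiation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing long noncoding RNA (lncRNA) biotypes across
    a neuronal differentiation time course. Classifies lncRNA genes into
    seven positional biotypes (divergent XH, convergent XT, antisense
    outside XO, antisense inside XI, sense downstream SD, sense upstream SU,
    intergenic IG) relative to protein-coding partners; filters and
    standardizes RPKM time-course matrices; performs fuzzy c-means soft
    clustering with marker-gene stage assignment; builds unsigned weighted
    co-expression networks with topological overlap module detection;
    infers mutual-information networks with data-processing-inequality
    pruning, hub ranking and multiedge-partner statistics; and scores
    transcript coding potential with the Fickett TESTCODE statistic and
    ORF coverage. A synthetic-data generator produces annotation,
    expression, network and sequence fixtures with known ground truth.
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
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    withr,
    knitr,
    rmarkdown,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
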