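Package: endosclust
Title: Spatio-Temporal Transcriptome Analysis of the Maize Endosperm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for spatio-temporal analysis of the
    maize endosperm transcriptome across three cell types (basal endosperm
    transfer layer, aleurone, starchy endosperm) and three developmental
    stages (8, 12 and 16 days after pollination). Implements novel long
    noncoding RNA discovery by a five-stage filter chain (expression,
    annotation overlap, length, open-reading-frame coding potential,
    small-RNA/transposon blacklist), four-fold spatial and temporal
    regulation calling with Venn partitioning, self-organizing-map
    co-expression clustering with cluster specificity labelling,
    hypergeometric enrichment with Benjamini-Hochberg correction for GO
    terms and gene catalogues, H3K27me3 peak interval-overlap association
    with chi-square testing, lncRNA/neighbour-gene expression correlation
    within a genomic window, and qPCR relative-quantification arithmetic.
    Ships a synthetic-data generator that emulates the full nine-sample
    design with planted structure so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    generics
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
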