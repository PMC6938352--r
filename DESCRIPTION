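Package: nilnet
Title: Introgression-Specific Differential Expression and Co-Expression
    Networks for Near-Isogenic Line RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of internode RNA-seq from pairs of near-isogenic
    maize lines (NILs) that differ only at an introgressed QTL region.
    Implements a four-step intersection procedure on TMM-normalized
    negative-binomial GLM likelihood-ratio tests to isolate
    introgression-specific differentially expressed genes, single pattern
    expression (SPE) calling, gene-trait Pearson correlation with an
    exact small-n significance rule, correlation-thresholded
    co-expression networks with connected-component modules,
    preferentially located motif (PLM) detection in promoters, and
    hypergeometric gene-set enrichment.  Ships a synthetic-data generator
    emulating the 2-pair x 2-allele study design for end-to-end testing,
    and a packaged transcription of the study's 125-gene summary table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    edgeR,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
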