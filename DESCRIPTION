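Package: chromcord
Title: Concordant Chromatin Accessibility and Conserved Markers in Paired
    Innate and Adaptive Lymphocyte Lineages
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative analysis toolkit for comparing innate lymphoid
    cell (ILC) subsets with their T helper (Th) counterparts across
    transcriptome and chromatin accessibility data. Derives conserved
    lineage and immune-response marker genesets from multi-study expression
    matrices (TPM normalisation, low-expression filtering, design-protected
    batch removal), classifies open chromatin regions as
    expression-concordant or subset-specific by a replicate-aware
    three-part accessibility rule, computes peak-geometry statistics
    (width, distance to transcription start site), and infers
    distinguishing transcription factors by position weight matrix scanning
    with exact dynamic-programming p-value calibration and hypergeometric
    motif enrichment. Ships a synthetic-study generator that plants ground
    truth for every stage so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    limma,
    mclust,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
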