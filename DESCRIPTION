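Package: mirhost
Title: Host-Gene-Based Interpretation of miRNA Dysregulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interprets miRNA dysregulation through host genes rather than
    predicted target genes. Assigns every miRNA precursor to its sense-strand
    host gene from GFF3 gene models under explicit cluster and
    sequence-family rules, quantifies co-dysregulation of miRNAs and their
    host genes, and runs hypergeometric over-representation analysis of the
    resulting host-gene list (with a target-gene mode for comparison)
    against GMT gene-set collections with Benjamini-Hochberg FDR control.
    Includes a seeded synthetic-data generator with planted ground truth and
    a packaged example encoding the PANK1/2/3-miR-107/-103a and
    USMG5-miR-1307 host relationships.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
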