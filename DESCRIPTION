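Package: pavscape
Title: Presence/Absence Gene Variation Analysis for Resequenced Plant Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls gene presence/absence (P/A) variation from inaccessible-region
    masks of resequenced consensus genomes, then characterizes the P/A landscape
    of a cohort: the absence-frequency spectrum, a random-sampling rarefaction
    model with logarithmic curve fit, sequence-divergence gene families and
    tandem gene clusters, covariation of nucleotide diversity with absence
    frequency, neighbor-joining trees on binary P/A profiles and on SNPs,
    chromosomal distribution relative to centromeres, and functional-category
    enrichment. Includes a fully specified synthetic-cohort generator with
    truth tables for end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
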