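Package: crosslinkr
Title: Cross-Link Site Analysis for CLIP and iCLIP cDNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein-RNA cross-link sites from mapped CLIP and iCLIP
    cDNA libraries using cDNA truncations and single-nucleotide deletions.
    Collapses PCR duplicates by random barcode, re-defines deletion sites that
    fall within TTT homopolymer context to the motif center, estimates the
    read-through versus truncated cDNA mixture from deletion proportions,
    profiles motif occurrence and enrichment around cross-link sites against a
    segment-randomized background, and scores YCAY motif clusters with a
    41-nucleotide sliding window, correlating cluster scores with cDNA counts.
    Includes a synthetic-data generator that plants YCAY clusters and TTT runs
    in a toy genome so every stage of the pipeline is testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    IRanges,
    data.table,
    jsonlite,
    methods,
    S4Vectors,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
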