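Package: bhlhscan
Title: Genome-Wide Characterization of Basic Helix-Loop-Helix Transcription
    Factor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for genome-wide surveys of the plant
    basic helix-loop-helix (bHLH) transcription factor family: position-specific
    scoring matrix detection and partitioning of the 55-residue bHLH domain,
    per-column conservation statistics, rule-based prediction of DNA-binding
    type (G-box, E-box, non-E-box, non-binder) from basic-region residues,
    promoter cis-regulatory element scanning against an IUPAC motif dictionary,
    exon-intron structure inference by spliced exact matching of CDS against
    genomic sequence, neighbor-joining phylogeny with bootstrap support and
    reference-based clade assignment, FPKM expression-tier calling with
    log2-transformed heatmap grouping, 2^-delta-delta-CT relative expression
    with significance tests, and homolog-projected protein-protein interaction
    networks. Includes seeded synthetic-data generators that produce every
    input the pipeline consumes together with a recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    withr
Config/testthat/edition: 3
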