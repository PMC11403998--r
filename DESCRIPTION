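Package: numtatlas
Title: Detection, Dating and Population Analysis of Nuclear Sequences of
    Mitochondrial Origin (NUMT)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for building an atlas of nuclear sequences
    of mitochondrial origin (NUMT). Detects NUMT in assembled genomes by
    seeded local alignment of a circularised mitochondrial consensus with
    reversed-sequence score-threshold calibration; detects non-reference NUMT
    insertions in short-read data from soft-clipped read breakpoints with a
    depth/identity/ratio filter cascade and per-sample genotyping; resolves
    cross-genome orthology of NUMT regions from one-to-one whole-genome
    alignment blocks and gene synteny; classifies insertion age from
    presence/absence patterns across species and dates insertions
    quantitatively with the allele-matching-ratio method and the
    Kimura-two-parameter distance method; and summarises carrier frequencies,
    polymorphism, breed clustering and genomic annotation. Ships a
    synthetic-data generator (mitochondrial evolution on a species tree,
    genomes with planted NUMT of known age, analytic paired-end alignments)
    so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    ape,
    rtracklayer,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
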