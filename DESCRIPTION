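Package: helvepan
Title: Repeat-Aware Comparative Genomics for Lactic Acid Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for families of closely related
    bacterial strains, built around dairy lactobacilli. Detects intra-genomic
    repeat pairs and classifies genomes into assembly-difficulty classes
    I/II/III; audits draft (short-read) assemblies against complete references
    for zero-coverage gaps and the annotated genes they miss; clusters
    protein-coding genes across genomes at high identity without paralog
    splitting and derives pan/core/accessory/unique partitions, randomized
    gene-accumulation curves and COG cross-tabulations; six-frame translates
    pseudogenes and tests GO biological-process terms for overrepresentation
    (classic Fisher and elim); and attributes multi-mapped metagenome reads to
    species, strain groups and individual genomes. Seeded synthetic-data
    generators produce every input with known ground truth so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    methods,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
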