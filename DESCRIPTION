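Package: IndelMarkers
Title: Design and In Silico Evaluation of Agarose-Scorable Indel Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts annotated insertion-deletion polymorphisms between
    inbred lines into PCR-ready molecular markers scorable on high-percentage
    agarose gels. Starting from a reference genome and per-inbred variant
    tracks (VCF or a tab-separated polymorphism-track export), the package
    filters Indels by net allele-length difference, designs flanking primer
    pairs with nearest-neighbor melting temperatures and short reference
    amplicons, checks genome-wide primer specificity by in silico PCR,
    predicts per-inbred products and amplification failures, and classifies
    markers as co-dominant, dominant, presence-absence, or non-polymorphic
    for any pair of inbreds. Utilities for inter-marker spacing statistics
    and evenly spaced marker selection support iterative fine-mapping, and a
    seeded simulator generates toy genomes and variant tracks with known
    ground truth for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
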