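Package: HBStools
Title: HIF-1 Binding Site Discovery, ChIP-qPCR Quantification and
    Protein-DNA Interface Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates candidate hypoxia-inducible factor (HIF-1) binding
    sites around a transcription start site (TSS) in genomic sequence
    using the conserved ACGTG core and the G(-2)/C(+5) flanking-nucleotide
    rule, on a strand-aware zero-free TSS-relative coordinate axis.  Also
    quantifies ChIP-qPCR fold enrichment (2^(IgG Ct - sample Ct)) and
    delta-delta-Ct relative expression from threshold-cycle tables, and
    computes protein-DNA interface metrics (distance-cutoff atom-pair
    contacts, residue contact maps, Kabsch-superposed RMSD and RMSF) on
    multi-model PDB structures.  Seeded synthetic-data generators with
    serialized ground truth exercise every stage without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
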