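Package: pprcleave
Title: Design and Verification of PPR-Protein-Guided Cleavage of Organelle Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retargeting pentatricopeptide-repeat (PPR) proteins to
    new organelle RNA targets and for verifying the induced transcript cleavage
    from sequencing readouts. Implements PPR-code match classification, binding
    prediction and minimal scaffold redesign; strand-aware genome/CDS coordinate
    conversion and mismatch-tolerant target-site scanning; transcript end
    mapping from circularized RT-PCR clones with consensus cleavage calling;
    per-position RNA-seq 5'-end profiling with local-background normalization
    and genotype comparison; intron splicing-efficiency, C-to-U editing-rate,
    adenylate energy-charge and flux-control-coefficient computations; and a
    deterministic synthetic organelle-transcriptome generator with recorded
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rsamtools,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
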