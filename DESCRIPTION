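Package: VarScribe
Title: Validation, Projection and Normalization of HGVS Sequence Variant Descriptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Parses sequence-variant descriptions in HGVS, pseudo-VCF and hybrid
    HGVS:VCF dialects, validates them against reference sequences and transcript
    alignment models (including transcript-genome base mismatches within aligned
    exons), projects variants between CDS, transcript, gene-region and chromosome
    coordinate frames and between genome builds, normalizes indels per the HGVS
    3'-rule (including shuffling across exon/intron junctions), interconverts
    genomic descriptions with VCF-style records, and predicts protein-level
    consequences by translate-and-diff (inversions included). Emits a
    multi-context validation report with corrective guidance, and ships a
    deterministic synthetic reference-bundle generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    utils,
    stats,
    Biostrings,
    jsonlite,
    vcfR,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
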