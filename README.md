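# VarScribe

Validation, projection and normalization of HGVS sequence-variant
descriptions, with VCF interconversion and protein-consequence prediction.

## The problem

Clinical reports, publications and variant databases describe sequence
variants in HGVS nomenclature (e.g. `NM_000088.3:c.589G>T`), while
high-throughput pipelines emit VCF records and aggregators use compact
pseudo-VCF identifiers (`1-150550916-G-A`). Moving between these worlds is
error-prone: stated reference bases may disagree with the reference
sequence, intronic positions written against a transcript
(`c.688+403C>T`) can only be verified against a genomic sequence, indels in
repeat tracts have many equivalent spellings (HGVS requires the most 3'
one, VCF the most 5'), and RefSeq transcripts may genuinely mismatch the
genome they are aligned to, so the *governing* sequence must be chosen per
coordinate frame. VarScribe implements that whole round trip for anyone who
curates, validates or converts variant descriptions.

## What it does

* **Parses** every common dialect: plain HGVS (`g.`/`c.`/`n.`), composed
  forms `NG_xxxx(NM_yyyy):c.…`, pseudo-VCF `1-150550916-G-A` /
  `1:150550916G>A`, hybrid HGVS:VCF (`NC_000016.9:g.2099572TC>T`), and
  gene-symbol-prefixed input (refused with corrective guidance).
* **Validates** stated bases against the governing sequence (transcript for
  exonic c./n. positions, genome for intronic offsets and g. positions) and
  auto-corrects mis-stated intron/exon boundary coordinates
  (`c.687+404` → `c.688+403`).
* **Projects** variants exactly between CDS, transcript, gene-region,
  chromosome and second-build frames by walking exon alignment CIGARs
  (strand-aware, mismatch-aware; builds are bridged via a shared
  transcript). Reference bases are re-read from the target, so a
  transcript–genome mismatch yields the correct, different base on each
  side.
* **Normalizes** per the HGVS 3'-rule: minimal representation, 3' shuffling
  (crossing exon/intron junctions where the repeat does), duplication
  detection — and the opposite, VCF left-alignment with anchor bases, for
  **bit-exact HGVS ↔ VCF interconversion** and batch VCF ingestion.
* **Predicts protein consequences** by translate-and-diff: extract the CDS
  (transcript governs), apply the edit (inversions included), translate
  both, diff the proteins (`p.(Thr47Arg)`, `p.(Ala2HisfsTer?)`, …).
* **Reports** every context at once — genomic description and pseudo-VCF
  per build, gene-region description when a RefSeqGene-like record covers
  the locus (it takes precedence over the chromosome in composed output),
  every overlapping transcript with its composed form and protein
  prediction — plus machine-readable diagnostics, as JSON or TSV.

A deterministic synthetic reference bundle (`generateFixture("TOY1")`)
stands in for curated reference services in tests and examples: two genome
builds related by a +24 shift, plus/minus-strand multi-exon genes, a
planted transcript–genome mismatch and a junction-spanning homopolymer.

## Worked example

```r
library(VarScribe)
rs <- generateFixture("TOY1", seed = 1, dir = tempfile())

report <- validateVariant("TX1.1:c.90+5T>A", rs, assembly = "TB1")
report
#> ValidationReport for "TX1.1:c.90+5T>A" (assembly TB1) -- validated
#>   TB1: CTY1.1:g.1105T>A  [CTY1-1105-T-A]
#>   TB2: CTY1.2:g.1129T>A  [CTY1-1129-T-A]
#>   gene region: GG1.1:g.205T>A
#>   TX1.1:c.90+5T>A  (GENE1)  p.?
#>     GG1.1(TX1.1):c.90+5T>A
```

The intronic substitution is verified against the genome (the transcript
has no intron bases), mapped to both builds with their pseudo-VCF
identifiers, expressed against the gene-region record `GG1.1` (which takes
precedence over the chromosome in the composed form), and given a protein
prediction (`p.?` — intronic, no coding change predicted).

A chromosome-level input maps to every overlapping transcript, through a
planted transcript–genome mismatch at this position (genome `A`,
transcript `C`):

```r
validateVariant("CTY1-1350-A-G", rs, assembly = "TB1")
#>   TB1: CTY1.1:g.1350A>G  [CTY1-1350-A-G]
#>   ...
#>   TX1.1:c.140C>G  (GENE1)  p.(Thr47Arg)
#>   TX2.1:c.98A>G   (GENE1)  p.(Lys33Arg)
```

A command-line wrapper is shipped in `inst/scripts/varscribe`
(`validate`, `batch`, `vcf2hgvs`, `refs`, `make-fixture`).

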