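---
title: "Validating, projecting and normalizing variant descriptions: methods"
author: "VarScribe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating, projecting and normalizing variant descriptions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VarScribe)
```

## Scope and model

VarScribe validates sequence-variant descriptions against a *reference
universe*: sequences (chromosomes, gene-region records, transcripts),
transcript alignment models, gene-region↔chromosome mappings, and
cross-references from LRG/Ensembl-style aliases to curated records. The
central modelling commitments are:

* **Interbase internally, 1-based at the surface.** All internal spans are
  0-based half-open; every printed HGVS coordinate is 1-based inclusive.
  Interbase arithmetic makes insertion points and CIGAR walking unambiguous;
  the conversion happens exactly once, at the parse/format and file-load
  boundaries.
* **Transcript models are per-assembly.** Each transcript stores one exon
  table per genome build (duplicated, not lifted on the fly), mirroring how
  curated transcript-alignment archives publish per-build mappings. Exon
  blocks carry CIGAR strings over `M`/`I`/`D`, where `M` may cover
  mismatching bases: a RefSeq-style transcript is *not* assumed to equal
  its genomic alignment.
* **The governing sequence is chosen per coordinate frame.** Exonic `c.`/
  `n.` positions are verified against the transcript sequence; intronic
  offsets and `g.` positions against the genome. This is what makes the
  planted TOY1 case work: `CTY1.1:g.1350A>G` and `TX1.1:c.140C>G` are the
  *same* variant even though the stated reference bases differ, and both
  produce the identical protein prediction because the CDS is always taken
  from the transcript.
* **Reference class by accession prefix.** Mapping is restricted to curated
  classes (chromosome, gene-region, coding/non-coding transcript, protein),
  inferred from a configurable prefix map (`NC_`/`NG_`/`NM_`/`NR_`/`NP_`
  and the fixture analogues `CTY`/`GG`/`TX`). Unversioned accessions
  resolve to the highest loaded version with a warning — permissive, but
  audible.

## Coordinate projection

`c. ↔ n.` arithmetic is closed-form around the CDS bounds (no position
zero; star positions count past the CDS end). `n. ↔ g.` projection walks
the exon CIGARs: `M` advances both frames, `I` only the transcript, `D`
only the genome. Positions falling inside `I`/`D` ops are refused with
explicit errors rather than nudged to a neighbour — the behaviour of a
variant overlapping a transcript–genome indel discrepancy is genuinely
undefined, so we fail loudly. Intronic offsets apply in transcript
orientation: plus-strand genes add the offset on the genome, minus-strand
genes subtract it. Mapping genome→transcript anchors an intronic position
to the *nearer* exon boundary; an exact mid-intron tie takes the `+`
offset from the preceding exon. The tie-break is arbitrary but must be
fixed for determinism; `+` keeps the anchor 5' of the position, matching
how donor-side offsets are conventionally written.

Projection between builds always bridges through a shared transcript
(endpoint-wise), never by raw offsetting, and gene-region frames project
through their region map. After any projection the stated reference bases
are re-read from the target sequence, so mismatched bases come out right
on each side by construction.

Intervals project endpoint-wise; if endpoints land in frames that cannot
be reconciled the projection fails rather than guessing.

## Normalization

Raw ref/alt pairs (hybrid HGVS:VCF input, VCF records, delins) are first
*minimized*: longest common prefix, then longest common suffix, trimmed;
the residue classifies as substitution, deletion, insertion or delins.
Indels are then slid 3'-ward (rotate-and-advance over repeats) as far as
the edited sequence is unchanged — the HGVS 3'-rule — and an insertion
that exactly equals the adjacent 5' sequence is re-classified as a
duplication (full-length match only; partial repeats stay insertions —
the strict rule is deterministic). `N` never matches during shuffling.

`g.`-frame normalization uses the chromosome's forward sense; `c./n.`
frame normalization uses the *genome-backed pre-mRNA in transcript
orientation*, so a shuffle can carry an edit across an exon/intron
junction and the result gains intronic offsets. On TOY1, deleting the last
three exon-1 Ts (`c.88_90delTTT`) lands in the junction homopolymer and
normalizes to `c.90+1_90+3delTTT` = `g.1101_1103delTTT`, the unique
maximal-position member of the equivalence class (checked against
exhaustive enumeration). Minus-strand genes therefore shuffle toward
genomic 5', keeping `g.` descriptions VCF-comparable while `c.`
descriptions obey the transcript's reading direction. `n.` variants of
non-coding transcripts are normalized identically to `c.` ones; nothing
in the nomenclature suggests they should differ.

VCF conversion is the mirror image: left-align, then anchor with the
preceding reference base (a variant at position 1 anchors with the
following base). The left-aligned VCF position is never 3' of the
HGVS start — a property the test suite fuzzes.

## Protein prediction

Predictions are computed by translate-and-diff: slice the CDS from the
transcript sequence, apply the edit by string surgery (an inversion
replaces the span by its reverse complement), translate both with the
standard code (stop rendered `*`, translation halts at the first stop,
trailing partial codons ignored), and diff. The diff trims the common
prefix, handles stop-loss (extension) and nonsense before suffix
trimming, then classifies substitution / delins / in-frame
deletion–duplication–insertion (repeated residues named at their most 3'
position, mirroring the nucleotide rule) / frameshift. Frameshifts are
named from the first changed residue with the stop position in the new
frame, or `Ter?` when no stop is reachable. Start-codon-disrupting edits
return `p.?` (unpredictable), as do variants not fully inside the CDS;
UTR-only and intronic variants report a no-protein result rather than
`p.(=)` — predicting silence from a non-coding change would overstate
what the computation shows. All output is parenthesized: these are
predictions, not observations.

## Validation pipeline and diagnostics

`validateVariant()` chains parse → usage guidance → boundary
auto-correction → reference agreement → projection to the selected build →
overlap search → per-transcript projection and normalization → protein
prediction → pseudo-VCF per build. Any *error* diagnostic short-circuits
into a diagnostics-only report. Diagnostics carry a stable code, a
severity and, for corrections, a suggested input that is itself
parseable. Severity and code taxonomy are this package's own design; the
guidance texts follow the conventions of interactive validators (gene
symbols are refused with the gene's valid transcripts listed; gene-region
`c.` positions without a transcript get candidate composed descriptions,
each flagged for resubmission; legacy `GENE_v003`-style designations are
redirected). Composed output prefers a covering gene-region record over
the chromosome and falls back to `chromosome(transcript)` with an info
diagnostic saying no gene-region record exists. Identity edits (ref =
alt, as VCF round trips produce) are accepted with a warning and an HGVS
`=` description — refusing them would break batch VCF processing.

The intronic-verification build is a required pipeline input (defaulting
to the bundle's configured default), because intronic `c.` positions are
only verifiable against genomic sequence.

## The synthetic bundle: what it emulates, what it does not

`generateFixture("TOY1", seed)` writes a complete bundle (FASTA +
transcript/region/cross-reference/assembly tables + a small VCF),
deterministically for a given seed. It emulates the structures the
algorithms must survive: multi-exon genes on both strands; two transcripts
sharing exons over one locus; a transcript–genome mismatch inside an
aligned exon (genome `A` at g.1350, transcript `C` at c.140, chosen so
the mismatch codon is sense in both frames); a T-homopolymer spanning the
exon-1/intron-1 junction (g.1097–1103, bounded by non-T bases so the
repeat tract is exact); a gene-region record at a fixed +900 offset; a
second build that is the first with 24 bases prepended; and
LRG/Ensembl-style aliases. Coding sequences are built from sampled sense
codons, so translation never hits a premature stop by accident.

What it does **not** emulate: alignment indels between transcript and
genome (`I`/`D` CIGAR ops — the code paths exist and are exercised as
refusals, but no fixture transcript carries them), multiple gene-region
records per gene, overlapping genes on opposite strands at one locus,
unversioned/withdrawn record histories, and the sheer scale of a real
genome. Passing tests therefore demonstrate the correctness of the
arithmetic and the pipeline's contracts on realistic *structures*, not
performance or coverage of every curation pathology in real reference
data.

Problem sizes were chosen to keep the whole suite desk-scale: a 2000-bp
chromosome, four transcripts, exhaustive round-trips over every footprint
position (~3,200 projections), 1,000 fuzzed indels for edit-equivalence,
300 enumerated shuffle classes, 500 grammar-fuzzed parses.

## Numerical and degenerate-input choices

* Empty input, base 0, inverted intervals, and multi-base ref/alt on
  non-`g.` frames are parse errors with the offending token quoted.
* Bounds violations name the sequence and its length.
* A deletion at position 1 (no 5' anchor) anchors with the following base
  in VCF output — the documented fallback.
* Gene conversion descriptions parse (syntax validation) but refuse
  projection and protein prediction with a dedicated error.
* Protein (`p.`) input is recognized and refused with guidance:
  back-translation is out of scope, predictions are output-only.
* Mitochondrial (`m.`) and RNA (`r.`) coordinate types are not accepted;
  the grammar covers `g./c./n.` input and `p.` output.

## Known limitations

* Normalization loads the full chromosome string as its context; fine for
  gene-scale and the bundled fixtures, wasteful for full-size human
  chromosomes (a windowed context would be the natural extension).
* Alleles, mosaicism and repeat-count notation (`c.6T[9]`) are outside the
  grammar.
* When several gene-region records could cover one locus the first loaded
  one wins; the bundle format carries one per gene.
* Cross-build bridging picks the first overlapping transcript mapped to
  both builds; transcripts disagreeing about a bridge would need a
  reconciliation policy the data here cannot inform.
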