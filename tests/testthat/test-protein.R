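# Protein consequence prediction: extract, apply, translate, diff.

toyCds <- "ATGGCATTCTAA"  # MAF*

test_that("extractCds slices the transcript sequence, never the genome", {
  rs <- toyRefSet()
  cds <- extractCds(rs@transcripts[["TX1.1"]], rs)
  expect_equal(nchar(cds), 240L)
  expect_identical(substr(cds, 1, 3), "ATG")
  expect_identical(substr(cds, 238, 240), "TAA")
  # c.140 is the planted mismatch: transcript C although the genome shows A
  expect_identical(substr(cds, 140, 140), "C")
  expect_error(extractCds(rs@transcripts[["TX4.1"]], rs),
               class = "vs_noncoding")
})

test_that("applyEditToCds performs exact string surgery, inversions included", {
  inv <- parseVariant("X.1:c.4_6inv")
  expect_identical(applyEditToCds(toyCds, inv), "ATGTGCTTCTAA")
  sub <- parseVariant("X.1:c.5C>T")
  expect_identical(applyEditToCds(toyCds, sub), "ATGGTATTCTAA")
  del <- parseVariant("X.1:c.4delG")
  expect_identical(applyEditToCds(toyCds, del), "ATGCATTCTAA")
  dup <- parseVariant("X.1:c.4_6dup")
  expect_identical(applyEditToCds(toyCds, dup), "ATGGCAGCATTCTAA")
  ins <- parseVariant("X.1:c.3_4insTTT")
  expect_identical(applyEditToCds(toyCds, ins), "ATGTTTGCATTCTAA")
  expect_error(applyEditToCds(toyCds, parseVariant("X.1:c.90+5T>A")),
               class = "vs_out_of_range")
})

test_that("translateCds matches the reference translator and halts at stops", {
  expect_identical(translateCds("ATGGCATTCTAA"), "MAF*")
  expect_identical(translateCds("ATG"), "M")
  expect_identical(translateCds("ATGTGCTTCTAA"), "MCF*")
  expect_identical(translateCds("ATGAA"), "M")  # trailing partial codon
  # independent cross-check against the Biostrings translator
  set.seed(9)
  for (i in 1:25) {
    nt <- paste(sample(c("A", "C", "G", "T"), 3 * sample(5:40, 1),
                       replace = TRUE), collapse = "")
    full <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt), no.init.codon = TRUE))
    want <- sub("(\\*).*$", "\\1", full)
    expect_identical(translateCds(nt), want, info = nt)
  }
})

test_that("diffProteins classifies the toy-CDS table as brute force does", {
  # inversion c.4_6inv: GCA -> TGC
  expect_identical(diffProteins("MAF*", "MCF*")$label, "p.(Ala2Cys)")
  # substitution c.5C>T: GCA -> GTA
  expect_identical(diffProteins("MAF*", "MVF*")$label, "p.(Ala2Val)")
  # frameshift c.4delG: no stop reachable in the 12-base toy CDS
  fs <- diffProteins("MAF*", "MHS")
  expect_identical(fs$label, "p.(Ala2HisfsTer?)")
  expect_identical(fs$kind, "frameshift")
  expect_identical(nchar(fs$ref_aa), 1L)
  # synonymous c.6A>T: GCA -> GCT
  syn <- diffProteins("MAF*", "MAF*", affectedCodon = 2L)
  expect_identical(syn$label, "p.(Ala2=)")
  # nonsense and extension classes
  expect_identical(diffProteins("MAFW*", "MA*")$label, "p.(Phe3Ter)")
  ext <- diffProteins("MA*", "MAQW*")
  expect_identical(ext$kind, "extension")
  expect_identical(ext$label, "p.(Ter3GlnextTer3)")
})

test_that("codon-2 substitutions agree with per-codon brute force", {
  # all 9 single-base substitutions in codon 2 (GCA) of the toy CDS
  for (p in 4:6) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(toyCds, p, p))) {
      altCds <- paste0(substr(toyCds, 1, p - 1), b,
                       substr(toyCds, p + 1, nchar(toyCds)))
      got <- diffProteins(translateCds(toyCds), translateCds(altCds),
                          affectedCodon = 2L)
      # brute-force oracle: compare codon by codon
      refCodon <- Biostrings::GENETIC_CODE[[substr(toyCds, 4, 6)]]
      altCodon <- Biostrings::GENETIC_CODE[[substr(altCds, 4, 6)]]
      if (refCodon == altCodon) {
        expect_identical(got$kind, "silent")
        expect_identical(got$start_residue, 2L)
      } else if (altCodon == "*") {
        expect_identical(got$alt_aa, "*")
      } else {
        expect_identical(got$kind, "substitution")
        expect_identical(got$ref_aa, refCodon)
        expect_identical(got$alt_aa, altCodon)
        expect_identical(got$start_residue, 2L)
      }
    }
  }
})

test_that("codon-aligned inversions equal delins by reverse complement", {
  set.seed(13)
  for (rep in 1:25) {
    codons <- sample(VarScribe:::SENSE_CODONS, 28, replace = TRUE)
    cds <- paste0("ATG", paste(codons, collapse = ""), "TAA")
    c1 <- sample(2:28, 1); c2 <- min(28, c1 + sample(0:3, 1))
    s <- 3 * (c1 - 1) + 1; e <- 3 * c2
    inv <- new("ParsedVariant", accession = "X.1", coordType = "c",
               start = hgvsPosition(s), end = hgvsPosition(e),
               edit = edit_("inversion"))
    rcz <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(cds, s, e))))
    di <- new("ParsedVariant", accession = "X.1", coordType = "c",
              start = hgvsPosition(s), end = hgvsPosition(e),
              edit = edit_("delins", alt = rcz))
    expect_identical(applyEditToCds(cds, inv), applyEditToCds(cds, di))
  }
})

test_that("predictProtein governs by the transcript and skips non-CDS edits", {
  rs <- toyRefSet()
  tx <- rs@transcripts[["TX1.1"]]
  intronic <- parseVariant("TX1.1:c.90+5T>A")
  expect_identical(predictProtein(intronic, tx, rs)$kind, "no_protein")
  utr <- parseVariant("TX1.1:c.-5G>A")
  expect_identical(predictProtein(utr, tx, rs)$kind, "no_protein")
  # mismatch governance: identical predictions from either input frame
  fromTx <- predictProtein(parseVariant("TX1.1:c.140C>G"), tx, rs)
  fromG <- predictProtein(
    projectVariant(parseVariant("CTY1.1:g.1350A>G"), "TX1.1", rs), tx, rs)
  expect_identical(fromTx$label, "p.(Thr47Arg)")
  expect_identical(fromG, fromTx)
})
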