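# CDS/transcript/genome arithmetic and variant projection.

test_that("CDS-transcript arithmetic has no position zero and honors UTRs", {
  rs <- toyRefSet()
  tx <- rs@transcripts[["TX1.1"]]   # CDS tx 11..250 (1-based)
  expect_equal(cdsToTx(hgvsPosition(1), tx)@base, 11L)
  expect_equal(cdsToTx(hgvsPosition(-1), tx)@base, 10L)
  expect_equal(cdsToTx(hgvsPosition(1, utr3 = TRUE), tx)@base, 251L)
  expect_equal(cdsToTx(hgvsPosition(90, 5L), tx)@offset, 5L)
  expect_equal(txToCds(hgvsPosition(11), tx)@base, 1L)
  expect_equal(txToCds(hgvsPosition(10), tx)@base, -1L)
  expect_true(txToCds(hgvsPosition(251), tx)@utr3)
  expect_error(cdsToTx(hgvsPosition(500), tx), "outside")
  expect_error(cdsToTx(hgvsPosition(1), rs@transcripts[["TX4.1"]]),
               class = "vs_noncoding")
})

test_that("transcript-to-genome projection handles offsets, builds, strands", {
  rs <- toyRefSet()
  tx1 <- rs@transcripts[["TX1.1"]]
  expect_equal(txToGenomic(hgvsPosition(100, 5L), tx1, "TB1")$pos, 1105L)
  expect_equal(txToGenomic(hgvsPosition(100, 5L), tx1, "TB2")$pos, 1129L)
  expect_identical(txToGenomic(hgvsPosition(100, 5L), tx1, "TB2")$chrom,
                   "CTY1.2")
  # minus strand: genomic position strictly decreases as +offset grows
  tx3 <- rs@transcripts[["TX3.1"]]
  gs <- vapply(1:20, function(k)
    txToGenomic(hgvsPosition(101, k), tx3, "TB1")$pos, integer(1))
  expect_equal(gs, seq(499L, 480L))
  expect_true(all(diff(gs) < 0))
  # guard rails
  expect_error(txToGenomic(hgvsPosition(50, 5L), tx1, "TB1"),
               class = "vs_nonboundary_offset")
  expect_error(txToGenomic(hgvsPosition(100, 201L), tx1, "TB1"),
               class = "vs_offset_exceeds_intron")
  expect_error(txToGenomic(hgvsPosition(100, 5L), tx1, "TB9"),
               class = "vs_no_path")
})

test_that("genome-to-transcript projection anchors introns to the nearer exon", {
  rs <- toyRefSet()
  tx1 <- rs@transcripts[["TX1.1"]]
  p <- genomicToTx(1105L, tx1, "TB1")
  expect_equal(c(p@base, p@offset), c(100L, 5L))
  # intron 1 spans g.1101-1300 (length 200); g.1200 is the +100 point
  expect_equal(genomicToTx(1200L, tx1, "TB1")@offset, 100L)
  expect_equal(genomicToTx(1201L, tx1, "TB1")@base, 101L)
  expect_equal(genomicToTx(1201L, tx1, "TB1")@offset, -100L)
  # exonic with planted mismatch: position only, bases play no role here
  p2 <- genomicToTx(1350L, tx1, "TB1")
  expect_equal(c(p2@base, p2@offset), c(150L, 0L))
  # minus strand mid-intron tie breaks to "+" from the preceding exon:
  # TX3.1 intron is g.401-499 (99 bases); g.450 is equidistant (50/50)
  tx3 <- rs@transcripts[["TX3.1"]]
  tie <- genomicToTx(450L, tx3, "TB1")
  expect_equal(c(tie@base, tie@offset), c(101L, 50L))
  expect_equal(genomicToTx(449L, tx3, "TB1")@offset, -49L)
  expect_error(genomicToTx(5L, tx1, "TB1"), class = "vs_out_of_footprint")
})

test_that("round-trip projection is the identity over entire footprints", {
  rs <- toyRefSet()
  for (acc in names(rs@transcripts)) {
    tx <- rs@transcripts[[acc]]
    for (asm in names(tx@exons)) {
      fp <- VarScribe:::txFootprint(tx, asm)
      for (g in seq(fp$span[1] + 1L, fp$span[2])) {
        np <- genomicToTx(g, tx, asm)
        g2 <- txToGenomic(np, tx, asm)$pos
        expect_identical(g2, g)
        if (identical(g2, g) == FALSE) break
      }
    }
  }
})

test_that("variant projection re-reads reference bases from the target", {
  rs <- toyRefSet()
  # transcript-genome mismatch: stated base differs by design on each side
  gv <- projectVariant(parseVariant("TX1.1:c.140C>G"), "TB1", rs)
  expect_identical(formatVariant(gv), "CTY1.1:g.1350A>G")
  tv <- projectVariant(parseVariant("CTY1.1:g.1350A>G"), "TX1.1", rs)
  expect_identical(formatVariant(tv), "TX1.1:c.140C>G")
  # build-to-build via the shared transcript
  b2 <- projectVariant(parseVariant("CTY1.1:g.1105T>A"), "TB2", rs,
                       assembly = "TB1")
  expect_identical(formatVariant(b2), "CTY1.2:g.1129T>A")
  # chromosome to gene region (offset 900 on TB1)
  rv <- projectVariant(parseVariant("CTY1.1:g.1105T>A"), "GG1.1", rs,
                       assembly = "TB1")
  expect_identical(formatVariant(rv), "GG1.1:g.205T>A")
  # conversions refuse projection
  expect_error(
    projectVariant(parseVariant("TX1.1:c.4_64conTX2.1:c.12_72"), "TB1", rs),
    class = "vs_conversion_unsupported")
})

test_that("projection through a minus-strand gene reverse-complements alleles", {
  rs <- toyRefSet()
  tx3 <- rs@transcripts[["TX3.1"]]
  txSeq <- rs@sequences[["TX3.1"]]
  set.seed(5)
  for (n in sample(1:202, 25)) {
    ref <- substr(txSeq, n, n)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- parseVariant(sprintf("TX3.1:n.%d%s>%s", n, ref, alt))
    gv <- projectVariant(v, "TB1", rs)
    expect_identical(gv@edit@alt,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(alt))))
    expect_identical(gv@edit@ref,
                     substr(rs@sequences[["CTY1.1"]], gv@start@base,
                            gv@start@base))
    # and the genomic base complements the transcript base (no mismatches
    # are planted on TX3.1)
    expect_identical(gv@edit@ref,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(ref))))
  }
})

test_that("applying an edit before or after projection edits the same bases", {
  # exhaustive over single-base substitutions at every exonic TX1.1 position
  rs <- toyRefSet()
  tx <- rs@transcripts[["TX1.1"]]
  txSeq <- rs@sequences[["TX1.1"]]
  chrom <- rs@sequences[["CTY1.1"]]
  rebuild <- function(genome) {
    # transcript from (edited) genome, re-applying the planted mismatch
    # wherever the edit did not overwrite it
    ex <- tx@exons[["TB1"]]$blocks
    s <- paste(vapply(seq_len(nrow(ex)), function(i)
      substr(genome, ex$g_start[i] + 1L, ex$g_end[i]), character(1)),
      collapse = "")
    s
  }
  for (n in seq_len(nchar(txSeq))) {
    ref <- substr(txSeq, n, n)
    alt <- if (ref == "A") "C" else "A"
    v <- new("ParsedVariant", accession = "TX1.1", coordType = "n",
             start = hgvsPosition(n), end = hgvsPosition(n),
             edit = edit_("substitution", ref, alt))
    editedTx <- oracleReplace(txSeq, n, n, alt)
    gv <- projectVariant(v, "TB1", rs)
    editedGenome <- oracleReplace(chrom, gv@start@base, gv@start@base,
                                  gv@edit@alt)
    back <- rebuild(editedGenome)
    if (n != 150L) substr(back, 150L, 150L) <- "C"  # mismatch governs
    expect_identical(back, editedTx, info = paste("n =", n))
  }
})
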