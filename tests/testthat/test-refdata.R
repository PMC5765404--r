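# Reference bundle: generation, loading, queries, referential integrity.

test_that("TOY1 generation is deterministic and loads with expected content", {
  rs <- toyRefSet()
  expect_length(rs@transcripts, 4L)
  expect_length(rs@regions, 1L)
  expect_equal(nrow(rs@crossRefs), 3L)
  expect_setequal(names(rs@assemblies), c("TB1", "TB2"))

  d1 <- file.path(tempdir(), "toy1-det-a")
  d2 <- file.path(tempdir(), "toy1-det-b")
  generateFixture("TOY1", seed = 7L, dir = d1)
  generateFixture("TOY1", seed = 7L, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)

  expect_error(generateFixture("TOY9"), "unknown fixture")
})

test_that("planted TOY1 features are in place", {
  rs <- toyRefSet()
  # junction homopolymer and its non-T bound
  expect_identical(getSequence(rs, "CTY1.1", 1098, 1103), "TTTTTT")
  expect_identical(getSequence(rs, "CTY1.1", 1104, 1104), "G")
  # transcript-genome mismatch at c.140 / g.1350
  expect_identical(getSequence(rs, "CTY1.1", 1350, 1350), "A")
  expect_identical(substr(getSequence(rs, "TX1.1"), 150, 150), "C")
  # exon 1 of TX1.1 equals the transcript head on both builds (+24 on TB2)
  expect_identical(getSequence(rs, "CTY1.1", 1001, 1100),
                   substr(getSequence(rs, "TX1.1"), 1, 100))
  expect_identical(getSequence(rs, "CTY1.2", 1025, 1124),
                   getSequence(rs, "CTY1.1", 1001, 1100))
})

test_that("getSequence slices, resolves aliases, and reports bounds errors", {
  rs <- toyRefSet()
  expect_identical(getSequence(rs, "CTY1.1", 1001, 1005),
                   substr(rs@sequences[["TX1.1"]], 1, 5))
  expect_identical(getSequence(rs, "LRG_1"), getSequence(rs, "GG1.1"))
  expect_identical(getSequence(rs, "LRG_1t1"), getSequence(rs, "TX1.1"))
  expect_error(getSequence(rs, "CTY1.1", 1, 0), "interval")
  expect_error(getSequence(rs, "CTY1.1", 1999, 2001), "length")
  expect_error(getSequence(rs, "NOPE9.9"), "resolve")
  # unversioned accessions resolve to the highest loaded version, warning
  expect_warning(s <- getSequence(rs, "CTY1", 1, 10), "unversioned")
  expect_identical(s, getSequence(rs, "CTY1.2", 1, 10))
})

test_that("resolveReference distinguishes records, aliases and gene symbols", {
  rs <- toyRefSet()
  r <- resolveReference(rs, "TX1.1")
  expect_identical(r$type, "transcript")
  expect_identical(accession(r$record), "TX1.1")
  g <- resolveReference(rs, "GENE1")
  expect_identical(g$type, "gene_symbol")
  expect_setequal(g$transcripts, c("TX1.1", "TX2.1"))
  e <- resolveReference(rs, "ENSTOY1")
  expect_identical(e$type, "transcript")
  expect_identical(accession(e$record), "TX1.1")
  expect_identical(resolveReference(rs, "WHAT")$type, "unknown")
})

test_that("overlap query matches fixture geometry and a brute-force scan", {
  rs <- toyRefSet()
  hit <- function(s, e) names(findOverlappingTranscripts(rs, "TB1", "CTY1.1",
                                                         s, e))
  expect_identical(hit(1105, 1105), "TX1.1")   # intron 1; TX2.1 starts 1201
  expect_setequal(hit(1350, 1350), c("TX1.1", "TX2.1"))
  expect_length(hit(1, 10), 0L)
  expect_setequal(hit(480, 600), c("TX3.1", "TX4.1"))
  expect_error(findOverlappingTranscripts(rs, "TB9", "CTY1.1", 1, 2),
               "available")

  bruteFootprint <- function(tx, asm) {
    b <- tx@exons[[asm]]$blocks
    c(min(b$g_start) + 1L, max(b$g_end))  # 1-based inclusive
  }
  set.seed(42)
  for (i in 1:40) {
    s <- sample(1:2000, 1); e <- s + sample(0:300, 1)
    expected <- names(Filter(function(tx) {
      fp <- bruteFootprint(tx, "TB1")
      s <= fp[2] && fp[1] <= e
    }, rs@transcripts))
    expect_setequal(hit(s, e), expected)
  }
})

test_that("exon CIGAR reconstruction reproduces every transcript sequence", {
  rs <- toyRefSet()
  # known planted mismatches: genome g.1350 (TB1 frame) reads C in TX1.1
  mismatches <- list(TX1.1 = c(TB1 = 1350L, TB2 = 1374L))
  for (acc in names(rs@transcripts)) {
    tx <- rs@transcripts[[acc]]
    for (asm in names(tx@exons)) {
      ex <- tx@exons[[asm]]
      chrom <- rs@sequences[[ex$chrom]]
      pieces <- vapply(seq_len(nrow(ex$blocks)), function(i) {
        b <- ex$blocks[i, ]
        s <- substr(chrom, b$g_start + 1L, b$g_end)
        if (tx@strand == "-")
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
        else s
      }, character(1))
      rebuilt <- paste(pieces, collapse = "")
      mm <- mismatches[[acc]]
      if (!is.null(mm) && asm %in% names(mm)) {
        np <- genomicToTx(mm[[asm]], tx, asm)
        substr(rebuilt, np@base, np@base) <- "C"
      }
      expect_identical(rebuilt, rs@sequences[[acc]],
                       info = paste(acc, asm))
    }
  }
})

test_that("region mappings agree with their chromosome slices", {
  rs <- toyRefSet()
  for (acc in names(rs@regions)) {
    reg <- rs@regions[[acc]]
    for (asm in names(reg$span)) {
      sp <- reg$span[[asm]]
      slice <- substr(rs@sequences[[reg$chromosome[[asm]]]],
                      sp[1] + 1L, sp[2])
      if (reg$orientation == "-")
        slice <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(slice)))
      expect_identical(rs@sequences[[acc]], slice, info = paste(acc, asm))
    }
  }
})

test_that("the loader rejects broken bundles and tolerates empty tables", {
  src <- toyDir()
  tamper <- function(mutate) {
    d <- tempfile("tampered_")
    dir.create(d)
    file.copy(list.files(src, full.names = TRUE), d)
    mutate(d)
    d
  }
  # transcript citing an unknown chromosome
  d <- tamper(function(d) {
    t <- read.table(file.path(d, "transcripts.tsv"), sep = "\t", header = TRUE)
    t$chromosome[t$accession == "TX1.1"] <- "CTY9.9"
    write.table(t, file.path(d, "transcripts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  expect_error(loadReferenceSet(d), "unknown sequence")
  unlink(d, recursive = TRUE)
  # missing file is named
  d <- tamper(function(d) unlink(file.path(d, "regions.tsv")))
  expect_error(loadReferenceSet(d), "regions.tsv")
  unlink(d, recursive = TRUE)
  # empty transcript table: sequences only, zero transcripts
  d <- tamper(function(d) {
    t <- read.table(file.path(d, "transcripts.tsv"), sep = "\t", header = TRUE)
    write.table(t[0, ], file.path(d, "transcripts.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })
  rs <- loadReferenceSet(d)
  expect_length(rs@transcripts, 0L)
  expect_gt(length(rs@sequences), 0L)
  unlink(d, recursive = TRUE)
})
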