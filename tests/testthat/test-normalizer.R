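# Minimal representation, 3'-rule shuffling, and full-variant normalization.

test_that("minimizeTriple trims common prefix and suffix and classifies", {
  d <- minimizeTriple(3, "GT", "G")
  expect_identical(d[c("kind", "start", "end")],
                   list(kind = "deletion", start = 4L, end = 4L))
  expect_identical(d$ref, "T")

  s <- minimizeTriple(5, "C", "T")
  expect_identical(s[c("kind", "start")], list(kind = "substitution",
                                               start = 5L))
  s2 <- minimizeTriple(2, "CGG", "CAG")
  expect_identical(s2[c("kind", "start", "ref", "alt")],
                   list(kind = "substitution", start = 3L, ref = "G",
                        alt = "A"))
  i <- minimizeTriple(4, "A", "ACG")
  expect_identical(i[c("kind", "start", "alt")],
                   list(kind = "insertion", start = 4L, alt = "CG"))
  di <- minimizeTriple(1, "ACGT", "AGGA")
  expect_identical(di$kind, "delins")
  id <- minimizeTriple(9, "ACG", "ACG")
  expect_identical(id$kind, "identity")
})

test_that("shuffle3 slides indels to the enumerated maximal position", {
  ctx <- "ACGTTTTGA"
  d <- shuffle3(list(kind = "deletion", start = 4L, end = 4L, ref = "T",
                     alt = ""), ctx)
  expect_identical(d[c("start", "end")], list(start = 7L, end = 7L))
  i <- shuffle3(list(kind = "insertion", start = 3L, end = 4L, ref = "",
                     alt = "T"), ctx)
  i <- VarScribe:::dupDetect(i, ctx)
  expect_identical(i[c("kind", "start", "end")],
                   list(kind = "duplication", start = 7L, end = 7L))
  # N bases never match
  n <- shuffle3(list(kind = "deletion", start = 2L, end = 2L, ref = "N",
                     alt = ""), "ANNNA")
  expect_identical(n$start, 2L)

  # property: equals the maximal member of the enumerated equivalence class
  set.seed(21)
  for (rep in 1:100) {
    ctx <- paste(sample(c("A", "C", "G", "T"), sample(20:60, 1),
                        replace = TRUE), collapse = "")
    if (runif(1) < 0.5) {
      L <- sample(1:4, 1)
      i0 <- sample(seq_len(nchar(ctx) - L), 1)
      got <- shuffle3(list(kind = "deletion", start = i0, end = i0 + L - 1L,
                           ref = "", alt = ""), ctx)
      want <- oracleMaxDeletion(ctx, i0, i0 + L - 1L)
      expect_equal(c(got$start, got$end), want)
    } else {
      p0 <- sample(0:nchar(ctx), 1)
      s0 <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1),
                         replace = TRUE), collapse = "")
      got <- shuffle3(list(kind = "insertion", start = p0, end = p0 + 1L,
                           ref = "", alt = s0), ctx)
      want <- oracleMaxInsertion(ctx, p0, s0)
      expect_identical(got$start, want$p)
      expect_identical(got$alt, want$alt)
    }
  }
})

test_that("hybrid triples normalize over the planted homopolymer run", {
  rs <- toyRefSet()
  v <- parseVariant("CTY1.1:g.1097TT>T")
  nv <- normalizeVariant(v, rs, "TB1")
  expect_identical(formatVariant(nv), "CTY1.1:g.1103delT")
  # substitutions normalize to themselves
  s <- parseVariant("CTY1.1:g.1105T>A")
  expect_identical(formatVariant(normalizeVariant(s, rs, "TB1")),
                   "CTY1.1:g.1105T>A")
  # identity triple yields the HGVS "=" form
  idv <- parseVariant("CTY1-1105-T-T", assembly = "TB1", refset = rs)
  expect_identical(normalizeVariant(idv, rs, "TB1")@edit@kind, "identity")
})

test_that("c.-frame normalization crosses the exon/intron junction", {
  rs <- toyRefSet()
  # deleting the last three exon-1 Ts is equivalent to deleting the first
  # three intron Ts; the maximal-3' placement (enumeration oracle over the
  # genomic context) is g.1101_1103, i.e. c.90+1_90+3
  chrom <- getSequence(rs, "CTY1.1")
  want <- oracleMaxDeletion(chrom, 1098, 1100)
  expect_identical(want, c(1101L, 1103L))

  nv <- normalizeVariant(parseVariant("TX1.1:c.88_90delTTT"), rs, "TB1")
  expect_identical(formatVariant(nv), "TX1.1:c.90+1_90+3delTTT")
  gv <- normalizeVariant(projectVariant(parseVariant("TX1.1:c.88_90delTTT"),
                                        "TB1", rs), rs, "TB1")
  expect_identical(formatVariant(gv), "CTY1.1:g.1101_1103delTTT")
})

test_that("normalization preserves the edited sequence and is idempotent", {
  set.seed(33)
  for (rep in 1:120) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    rs <- miniRefSet(ctx)
    pos <- sample(5:50, 1)
    ref <- substr(ctx, pos, pos + sample(0:4, 1))
    alt <- paste(sample(c("A", "C", "G", "T"), sample(1:5, 1),
                        replace = TRUE), collapse = "")
    if (ref == alt) next
    v <- new("ParsedVariant", accession = "MC1.1", coordType = "g",
             start = hgvsPosition(pos),
             end = hgvsPosition(pos + nchar(ref) - 1L),
             edit = edit_("delins", ref = ref, alt = alt),
             assembly = "MB1")
    nv <- normalizeVariant(v, rs, "MB1")
    expect_identical(oracleApplyGVariant(ctx, nv),
                     oracleApplyVcf(ctx, pos, ref, alt),
                     info = formatVariant(v))
    nv2 <- normalizeVariant(nv, rs, "MB1")
    expect_identical(formatVariant(nv2), formatVariant(nv))
  }
})
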