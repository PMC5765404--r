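# Reference agreement, boundary auto-correction, guidance, full reports.

test_that("reference agreement picks the governing sequence per coordinate", {
  rs <- toyRefSet()
  # genome governs g. positions: g.1350 is A, not C
  d <- checkReferenceAgreement(parseVariant("CTY1.1:g.1350C>A"), rs, "TB1")
  expect_length(d, 1L)
  expect_identical(d[[1]]@code, "ref_mismatch")
  expect_match(d[[1]]@message, "expected A")
  # transcript governs exonic c. positions: c.140 is C there
  expect_length(checkReferenceAgreement(parseVariant("TX1.1:c.140C>G"),
                                        rs, "TB1"), 0L)
  expect_length(checkReferenceAgreement(parseVariant("CTY1.1:g.1350A>G"),
                                        rs, "TB1"), 0L)
  # genome governs intronic offsets (g.1105 = T)
  expect_length(checkReferenceAgreement(parseVariant("TX1.1:c.90+5T>A"),
                                        rs, "TB1"), 0L)
  d2 <- checkReferenceAgreement(parseVariant("TX1.1:c.90+5G>A"), rs, "TB1")
  expect_identical(d2[[1]]@code, "ref_mismatch")
  # stated deletion bases are compared over the whole span
  d3 <- checkReferenceAgreement(parseVariant("TX1.1:c.88_90delAAA"),
                                rs, "TB1")
  expect_identical(d3[[1]]@code, "ref_mismatch")
})

test_that("intron boundary auto-correction is exact and idempotent", {
  rs <- toyRefSet()
  tx <- rs@transcripts[["TX1.1"]]
  # c.89+6 anchors one base short of the boundary: g.1099+6 = g.1105 = c.90+5
  bc <- correctIntronBoundary(parseVariant("TX1.1:c.89+6T>A"), tx, rs, "TB1")
  expect_identical(formatVariant(bc$variant), "TX1.1:c.90+5T>A")
  expect_length(bc$diagnostics, 1L)
  expect_identical(bc$diagnostics[[1]]@code, "boundary_corrected")
  expect_identical(bc$diagnostics[[1]]@suggestion, "TX1.1:c.90+5T>A")
  # correct anchors pass through with no diagnostic
  ok <- correctIntronBoundary(parseVariant("TX1.1:c.90+5T>A"), tx, rs, "TB1")
  expect_identical(formatVariant(ok$variant), "TX1.1:c.90+5T>A")
  expect_length(ok$diagnostics, 0L)
  # idempotence
  again <- correctIntronBoundary(bc$variant, tx, rs, "TB1")
  expect_identical(formatVariant(again$variant), formatVariant(bc$variant))
  expect_length(again$diagnostics, 0L)
  # the suggested input is itself parseable
  expect_s4_class(parseVariant(bc$diagnostics[[1]]@suggestion),
                  "ParsedVariant")
})

test_that("usage guidance covers gene symbols, NG:c., legacy and non-coding", {
  rs <- toyRefSet()
  g <- usageGuidance(parseVariant("GENE1:c.10A>T"), rs)
  expect_identical(g[[1]]@severity, "error")
  expect_identical(g[[1]]@code, "gene_symbol_not_allowed")
  expect_setequal(g[[1]]@suggestion, c("TX1.1:c.10A>T", "TX2.1:c.10A>T"))

  w <- usageGuidance(parseVariant("GG1.1:c.90+5T>A"), rs)
  expect_identical(w[[1]]@severity, "warning")
  expect_identical(w[[1]]@code, "gene_region_c_position")
  expect_true("GG1.1(TX1.1):c.90+5T>A" %in% w[[1]]@suggestion)
  expect_true("GG1.1(TX2.1):c.90+5T>A" %in% w[[1]]@suggestion)

  leg <- usageGuidance(parseVariant("GG1.1(GENE1_v003):c.90+5T>A"), rs)
  expect_identical(leg[[1]]@code, "legacy_designation")
  expect_identical(leg[[1]]@suggestion, "GG1.1:c.90+5T>A")

  nc <- usageGuidance(parseVariant("TX4.1:c.10A>T"), rs)
  expect_identical(nc[[1]]@code, "coding_position_on_noncoding")
  expect_identical(nc[[1]]@suggestion, "TX4.1:n.10A>T")
})

test_that("a validated intronic variant reports every reference context", {
  rs <- toyRefSet()
  r <- validateVariant("TX1.1:c.90+5T>A", rs, "TB1")
  expect_true(isValid(r))
  expect_identical(unname(genomicDescriptions(r)["TB1"]),
                   "CTY1.1:g.1105T>A")
  expect_identical(unname(genomicDescriptions(r)["TB2"]),
                   "CTY1.2:g.1129T>A")
  expect_identical(unname(pseudoVcf(r)["TB1"]), "CTY1-1105-T-A")
  expect_identical(unname(pseudoVcf(r)["TB2"]), "CTY1-1129-T-A")
  expect_identical(r@region$hgvs, "GG1.1:g.205T>A")
  expect_identical(names(r@transcriptResults), "TX1.1")  # intron 1 only
  expect_identical(r@transcriptResults[["TX1.1"]]$composed,
                   "GG1.1(TX1.1):c.90+5T>A")
  expect_identical(r@transcriptResults[["TX1.1"]]$protein$kind, "no_protein")
  expect_identical(r@transcriptResults[["TX1.1"]]$geneSymbol, "GENE1")
})

test_that("a pseudo-VCF input maps onto all overlapping transcripts", {
  rs <- toyRefSet()
  r <- validateVariant("CTY1-1350-A-G", rs, "TB1")
  expect_true(isValid(r))
  expect_setequal(names(r@transcriptResults), c("TX1.1", "TX2.1"))
  expect_identical(unname(transcriptDescriptions(r)["TX1.1"]),
                   "TX1.1:c.140C>G")
  expect_identical(unname(transcriptDescriptions(r)["TX2.1"]),
                   "TX2.1:c.98A>G")
  expect_identical(unname(proteinPredictions(r)["TX1.1"]), "p.(Thr47Arg)")
})

test_that("error diagnostics short-circuit into a diagnostics-only report", {
  rs <- toyRefSet()
  r <- validateVariant("GENE1:c.10A>T", rs, "TB1")
  expect_false(isValid(r))
  expect_length(r@transcriptResults, 0L)
  expect_length(r@genomic, 0L)
  expect_true("gene_symbol_not_allowed" %in% diagnosticCodes(r))

  r2 <- validateVariant("CTY1.1:g.1350C>A", rs, "TB1")
  expect_false(isValid(r2))
  expect_true("ref_mismatch" %in% diagnosticCodes(r2))

  r3 <- validateVariant("", rs, "TB1")
  expect_true("parse_error" %in% diagnosticCodes(r3))

  r4 <- validateVariant("TX1.1:c.4_64conTX2.1:c.12_72", rs, "TB1")
  expect_true("conversion_unsupported" %in% diagnosticCodes(r4))

  r5 <- validateVariant("NP_1.1:p.(Thr2Arg)", rs, "TB1")
  expect_true("protein_input" %in% diagnosticCodes(r5))
})

test_that("identity edits warn and render as the HGVS '=' description", {
  rs <- toyRefSet()
  r <- validateVariant("CTY1-1105-T-T", rs, "TB1")
  expect_true(isValid(r))
  expect_true("identity_variant" %in% diagnosticCodes(r))
  expect_match(unname(genomicDescriptions(r)["TB1"]), "=$")
})

test_that("chromosome fallback composed form carries an info diagnostic", {
  rs <- toyRefSet()
  # GENE2 has no gene-region record: composed forms fall back to CTY1.1(...)
  ref <- substr(getSequence(rs, "TX3.1"), 40, 40)  # c.30 = n.40
  alt <- if (ref == "G") "C" else "G"
  r <- validateVariant(sprintf("TX3.1:c.30%s>%s", ref, alt), rs, "TB1")
  expect_true(isValid(r))
  expect_true("no_gene_region_record" %in% diagnosticCodes(r))
  expect_match(r@transcriptResults[["TX3.1"]]$composed, "^CTY1\\.1\\(TX3\\.1\\)")
  expect_length(r@region, 0L)
})

test_that("boundary correction inside validate() carries the suggestion", {
  rs <- toyRefSet()
  r <- validateVariant("TX1.1:c.89+6T>A", rs, "TB1")
  expect_true(isValid(r))
  expect_true("boundary_corrected" %in% diagnosticCodes(r))
  expect_identical(unname(transcriptDescriptions(r)["TX1.1"]),
                   "TX1.1:c.90+5T>A")
})

test_that("reports serialize to JSON and TSV deterministically", {
  rs <- toyRefSet()
  r <- validateVariant("TX1.1:c.90+5T>A", rs, "TB1")
  j1 <- reportToJson(r)
  j2 <- reportToJson(validateVariant("TX1.1:c.90+5T>A", rs, "TB1"))
  expect_identical(j1, j2)
  parsed <- jsonlite::fromJSON(j1, simplifyVector = FALSE)
  expect_identical(parsed$input, "TX1.1:c.90+5T>A")
  expect_identical(parsed$genomic$TB1$pseudoVcf, "CTY1-1105-T-A")
  tsv <- reportToTsv(r)
  expect_true(all(c("context", "value") %in% names(tsv)))
  expect_true("pseudo_vcf:TB1" %in% tsv$context)
})
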