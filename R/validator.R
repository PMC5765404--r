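## Validation pipeline: parse -> resolve -> usage guidance -> boundary
## auto-correction -> reference agreement -> projection to the genome ->
## overlap search -> projection to every overlapping transcript ->
## per-context normalization -> protein prediction -> pseudo-VCF per build.
## Any error diagnostic short-circuits; the report then carries diagnostics
## only.  Composed output prefers a gene-region record over the chromosome
## and falls back to chromosome(transcript) with an info diagnostic when no
## gene-region record exists.

statedRefDiagnostics <- function(v, refset, assembly) {
  e <- v@edit
  if (is.na(e@ref) ||
      !(e@kind %in% c("substitution", "deletion", "duplication",
                      "inversion", "identity", "delins")))
    return(list())
  expected <-
    if (v@coordType == "g") {
      acc <- resolveAccession(refset, v@accession, warnUnversioned = FALSE)
      tryCatch(genomicRefSlice(refset, acc, v@start@base, v@end@base),
               error = function(err) NULL)
    } else {
      res <- resolveReference(refset, v@accession)
      if (res$type != "transcript") return(list())
      tx <- res$record
      txAsm <- if (assembly %in% names(tx@exons)) assembly
               else names(tx@exons)[1L]
      tryCatch(governingBases(toTxFrame(v@start, v, tx),
                              toTxFrame(v@end, v, tx), tx, txAsm, refset),
               error = function(err) NULL)
    }
  if (is.null(expected))
    return(list(diagnostic("error", "interval_out_of_bounds",
                           sprintf("interval %s_%s lies outside %s",
                                   formatPosition(v@start),
                                   formatPosition(v@end), v@accession))))
  if (!identical(expected, e@ref))
    return(list(diagnostic("error", "ref_mismatch",
      sprintf("the stated reference bases do not match %s: expected %s at %s.%s, description states %s",
              v@accession, expected, v@coordType,
              formatInterval(v@start, v@end), e@ref))))
  list()
}

#' Check a variant's stated bases against the governing reference
#'
#' Stated reference bases (a substitution's ref, delNNN, dupNNN, invNNN
#' spans) are compared against the governing sequence: the transcript
#' sequence for exonic c./n. positions, the genomic sequence for intronic
#' offsets and g. positions.  A mismatch produces an error diagnostic
#' quoting expected versus stated bases.
#'
#' @param v a parsed \linkS4class{ParsedVariant} with resolvable coordinates
#' @param refset a \linkS4class{ReferenceSet}
#' @param assembly build label
#' @return list of \linkS4class{Diagnostic} (empty when consistent)
#' @export
checkReferenceAgreement <- function(v, refset, assembly = NULL) {
  assembly <- assembly %||% v@assembly %||% refset@config$defaultAssembly
  statedRefDiagnostics(v, refset, assembly)
}

#' Auto-correct mis-stated intron/exon boundary coordinates
#'
#' For an intronic c./n. position whose anchor base is not a true exon
#' boundary in the offset's direction, computes the intended genomic
#' position (genomic coordinate of the stated anchor base, then the offset
#' applied in transcript orientation), re-projects it, and returns the most
#' probable valid description together with a warning carrying it.
#' Boundary-correct input passes through unchanged; the operation is
#' idempotent.
#'
#' @param v a c./n.-frame \linkS4class{ParsedVariant}
#' @param tx its \linkS4class{TranscriptRecord}
#' @param refset a \linkS4class{ReferenceSet}
#' @param assembly build label
#' @return list(variant = possibly corrected \linkS4class{ParsedVariant},
#'   diagnostics = list of \linkS4class{Diagnostic})
#' @export
correctIntronBoundary <- function(v, tx, refset, assembly = NULL) {
  assembly <- assembly %||% v@assembly %||% refset@config$defaultAssembly
  if (is.na(assembly)) assembly <- refset@config$defaultAssembly
  txAsm <- if (assembly %in% names(tx@exons)) assembly else names(tx@exons)[1L]
  diags <- list()
  corrected <- FALSE
  fixPos <- function(pos) {
    if (pos@offset == 0L) return(pos)
    n <- toTxFrame(pos, v, tx)
    ok <- tryCatch({
      txToGenomic(n, tx, txAsm, strict = TRUE)
      TRUE
    }, vs_nonboundary_offset = function(e) FALSE)
    if (ok) return(pos)
    gAnchor <- txToGenomic(hgvsPosition(n@base), tx, txAsm)$pos
    gIntended <- if (tx@strand == "+") gAnchor + n@offset
                 else gAnchor - n@offset
    nFixed <- genomicToTx(gIntended, tx, txAsm)   # errors if out of footprint
    corrected <<- TRUE
    fromTxFrame(nFixed, v@coordType, tx)
  }
  out <- v
  out@start <- fixPos(v@start)
  out@end <- fixPos(v@end)
  if (corrected) {
    sug <- formatVariant(out)
    diags <- list(diagnostic("warning", "boundary_corrected",
      sprintf("the stated intron/exon boundary coordinates are not correct; automatically re-mapped to the nearest exon boundary, most probable valid description: %s",
              sug),
      suggestion = sug))
  }
  list(variant = out, diagnostics = diags)
}

#' Usage guidance for problematic reference choices
#'
#' Produces the corrective guidance the validator attaches before mapping:
#' gene symbols in place of reference sequences (an error listing the
#' gene's valid transcripts), gene-region (RefSeqGene-like) accessions used
#' with c. positions and no companion transcript (a warning enumerating
#' candidate composed descriptions, each of which must be resubmitted to
#' determine whether it is valid), legacy composed designations, and c.
#' positions on non-coding transcripts (use n.).
#'
#' @param v a parsed \linkS4class{ParsedVariant}
#' @param refset a \linkS4class{ReferenceSet}
#' @return list of \linkS4class{Diagnostic}
#' @export
usageGuidance <- function(v, refset) {
  diags <- list()
  if (v@inputKind == "gene_symbol_style") {
    sym <- v@accession
    res <- resolveReference(refset, sym)
    cands <- if (res$type == "gene_symbol") res$transcripts else character(0)
    sugg <- vapply(cands, function(acc) {
      vv <- v; vv@accession <- acc
      tx <- refset@transcripts[[acc]]
      if (v@coordType == "c" && !isCoding(tx)) vv@coordType <- "n"
      formatVariant(vv)
    }, character(1))
    return(list(diagnostic("error", "gene_symbol_not_allowed",
      sprintf("HGVS nomenclature does not allow a gene symbol (%s) in place of a valid reference sequence; candidate transcript reference sequences for this gene: %s. The corrected description must be resubmitted to determine whether it is valid",
              sym, paste(cands, collapse = ", ")),
      suggestion = unname(sugg))))
  }
  if (!is.na(v@legacyCompanion)) {
    vv <- v; vv@legacyCompanion <- NA_character_
    sug <- formatVariant(vv)
    diags <- c(diags, list(diagnostic("warning", "legacy_designation",
      sprintf("\"%s\" is a legacy transcript designation, not a reference sequence; for assistance resubmit %s to obtain the supported composed descriptions",
              v@legacyCompanion, sug),
      suggestion = sug)))
    return(diags)
  }
  if (v@coordType %in% c("c", "n") && is.na(v@companion)) {
    acc <- suppressWarnings(resolveAccession(refset, v@accession))
    if (!is.na(acc) &&
        identical(unname(refset@moltype[acc]), "gene_region")) {
      reg <- refset@regions[[acc]]
      cands <- character(0)
      if (!is.null(reg)) {
        for (txAcc in names(refset@transcripts)) {
          tx <- refset@transcripts[[txAcc]]
          for (asm in intersect(names(tx@exons), names(reg$span))) {
            fp <- txFootprint(tx, asm)
            if (fp$chrom == reg$chromosome[[asm]] &&
                fp$span[1] >= reg$span[[asm]][1] &&
                fp$span[2] <= reg$span[[asm]][2]) {
              vv <- v; vv@companion <- acc; vv@accession <- txAcc
              if (v@coordType == "c" && !isCoding(tx)) vv@coordType <- "n"
              cands <- c(cands, formatVariant(vv, style = "composed"))
              break
            }
          }
        }
      }
      diags <- c(diags, list(diagnostic("warning", "gene_region_c_position",
        sprintf("%s.PositionVariation descriptions on a gene-region record should not be used unless a transcript reference sequence has also been provided, e.g. %s(<transcript>):%s.PositionVariation; candidate composed descriptions: %s. Each must be subsequently submitted to determine whether it is valid",
                v@coordType, acc, v@coordType,
                paste(cands, collapse = ", ")),
        suggestion = unname(cands))))
      return(diags)
    }
  }
  if (v@coordType == "c") {
    res <- resolveReference(refset, v@accession)
    if (res$type == "transcript" && !isCoding(res$record)) {
      vv <- v; vv@coordType <- "n"
      sug <- formatVariant(vv)
      diags <- c(diags, list(diagnostic("error", "coding_position_on_noncoding",
        sprintf("%s is a non-coding transcript: c. positions are undefined; the non-coding variant type (n.) is fully compliant, e.g. %s",
                v@accession, sug),
        suggestion = sug)))
    }
  }
  diags
}

failReport <- function(input, assembly, diags) {
  new("ValidationReport", input = input, assembly = assembly %||% NA_character_,
      ok = FALSE, diagnostics = diags)
}

#' Validate a variant description against a reference set
#'
#' The full pipeline: the description is parsed (any dialect), checked for
#' HGVS-compliance and usage problems, auto-corrected at intron/exon
#' boundaries where possible, verified against the governing reference
#' sequence, projected to the genome of the selected build and onto every
#' overlapping curated transcript, normalized per context (HGVS 3'-rule),
#' translated into a protein prediction per coding transcript, and rendered
#' as pseudo-VCF per supported build.
#'
#' @param text the variant description
#' @param refset a \linkS4class{ReferenceSet}
#' @param assembly selected build label (default: the config default)
#' @return a \linkS4class{ValidationReport}
#' @export
validateVariant <- function(text, refset, assembly = NULL) {
  assembly <- assembly %||% refset@config$defaultAssembly
  diags <- list()

  v <- tryCatch(parseVariant(text, assembly = assembly, refset = refset),
    vs_protein_input = function(e)
      diagnostic("error", "protein_input", conditionMessage(e)),
    vs_parse_error = function(e)
      diagnostic("error", "parse_error", conditionMessage(e)))
  if (is(v, "Diagnostic")) return(failReport(text, assembly, list(v)))

  if (!(assembly %in% names(refset@assemblies)))
    return(failReport(text, assembly, list(diagnostic("error",
      "unknown_assembly",
      sprintf("unknown assembly %s; available: %s", assembly,
              paste(names(refset@assemblies), collapse = ", "))))))

  ## usage guidance; gene-symbol and non-coding-c. guidance are errors,
  ## gene-region-c. and legacy guidance end in a diagnostics-only report
  g <- usageGuidance(v, refset)
  diags <- c(diags, g)
  sev <- vapply(diags, function(d) d@severity, character(1))
  if (any(sev == "error")) return(failReport(text, assembly, diags))
  if (any(vapply(diags, function(d)
        d@code %in% c("gene_region_c_position", "legacy_designation"),
        logical(1))))
    return(new("ValidationReport", input = text, assembly = assembly,
               ok = TRUE, diagnostics = diags))

  if (v@edit@kind == "conversion") {
    diags <- c(diags, list(diagnostic("error", "conversion_unsupported",
      "conversion mapping unsupported: the description is syntactically valid but cannot be projected between reference sequences or to a protein prediction")))
    return(failReport(text, assembly, diags))
  }

  ## resolve the primary reference
  tx <- NULL
  if (v@coordType %in% c("c", "n")) {
    res <- resolveReference(refset, v@accession)
    if (res$type != "transcript")
      return(failReport(text, assembly, c(diags, list(diagnostic("error",
        "unknown_reference",
        sprintf("cannot resolve %s to a supported transcript reference sequence",
                v@accession))))))
    if (res$accession != v@accession) {
      diags <- c(diags, list(diagnostic("info", "alias_resolved",
        sprintf("%s resolved to the sequence-identical curated record %s",
                v@accession, res$accession))))
      v@accession <- res$accession
    }
    tx <- res$record
  } else {
    acc <- suppressWarnings(resolveAccession(refset, v@accession))
    if (is.na(acc))
      acc <- chromAccessionForToken(v@accession, assembly, refset)
    if (is.na(acc) || !(acc %in% names(refset@sequences)))
      return(failReport(text, assembly, c(diags, list(diagnostic("error",
        "unknown_reference",
        sprintf("cannot resolve reference %s", v@accession))))))
    if (acc != v@accession) v@accession <- acc
  }

  if (v@edit@kind == "identity")
    diags <- c(diags, list(diagnostic("warning", "identity_variant",
      "the stated reference and observed alleles are identical; this describes no change (HGVS \"=\")")))

  ## boundary auto-correction for intronic c./n. coordinates
  if (!is.null(tx) && (v@start@offset != 0L || v@end@offset != 0L)) {
    bc <- tryCatch(correctIntronBoundary(v, tx, refset, assembly),
                   vs_error = function(e)
                     diagnostic("error", "boundary_error", conditionMessage(e)))
    if (is(bc, "Diagnostic"))
      return(failReport(text, assembly, c(diags, list(bc))))
    v <- bc$variant
    diags <- c(diags, bc$diagnostics)
  }

  ## reference agreement against the governing sequence
  agree <- checkReferenceAgreement(v, refset, assembly)
  diags <- c(diags, agree)
  if (any(vapply(agree, function(d) d@severity == "error", logical(1))))
    return(failReport(text, assembly, diags))

  ## project to the genome of the selected build, then normalize
  gv <- tryCatch(variantToGenomic(v, refset, assembly),
                 vs_error = function(e)
                   diagnostic("error", "projection_error", conditionMessage(e)))
  if (is(gv, "Diagnostic"))
    return(failReport(text, assembly, c(diags, list(gv))))
  ngv <- normalizeVariant(gv, refset, assembly)

  genomic <- list()
  genomic[[assembly]] <- list(
    hgvs = formatVariant(ngv),
    normalized = formatVariant(ngv),
    pseudoVcf = tryCatch(emitPseudoVcf(ngv, refset, assembly),
                         vs_error = function(e) NA_character_))
  for (other in setdiff(names(refset@assemblies), assembly)) {
    og <- tryCatch(crossBuildGenomic(ngv, refset, other),
                   vs_error = function(e) NULL)
    if (is.null(og)) {
      diags <- c(diags, list(diagnostic("info", "no_build_bridge",
        sprintf("no transcript bridges this variant to assembly %s", other))))
      next
    }
    ong <- normalizeVariant(og, refset, other)
    genomic[[other]] <- list(
      hgvs = formatVariant(ong),
      normalized = formatVariant(ong),
      pseudoVcf = tryCatch(emitPseudoVcf(ong, refset, other),
                           vs_error = function(e) NA_character_))
  }

  ## gene-region description (RefSeqGene-like precedence over chromosome)
  region <- list()
  regionAcc <- NA_character_
  for (acc in names(refset@regions)) {
    reg <- refset@regions[[acc]]
    if (assembly %in% names(reg$span) &&
        reg$chromosome[[assembly]] == ngv@accession &&
        ngv@start@base > reg$span[[assembly]][1] &&
        ngv@end@base <= reg$span[[assembly]][2]) {
      rv <- chromosomeToRegion(ngv, refset, acc)
      region <- list(accession = acc, hgvs = formatVariant(rv))
      regionAcc <- acc
      break
    }
  }

  ## map onto every overlapping curated transcript
  overl <- findOverlappingTranscripts(refset, assembly, ngv@accession,
                                      ngv@start@base, ngv@end@base)
  txResults <- list()
  for (otx in overl) {
    tv <- tryCatch(genomicToTranscriptVariant(ngv, otx, refset, assembly),
                   vs_error = function(e) NULL)
    if (is.null(tv)) {
      diags <- c(diags, list(diagnostic("warning", "transcript_projection_failed",
        sprintf("the variant could not be projected onto %s", otx@accession))))
      next
    }
    ntv <- normalizeVariant(tv, refset, assembly)
    composedPrefix <- if (!is.na(regionAcc)) regionAcc else ngv@accession
    ntvC <- ntv; ntvC@companion <- composedPrefix
    prot <- if (isCoding(otx)) predictProtein(ntv, otx, refset) else NULL
    txResults[[accession(otx)]] <- list(
      accession = accession(otx),
      hgvs = formatVariant(ntv),
      normalized = formatVariant(ntv),
      composed = formatVariant(ntvC, style = "composed"),
      geneSymbol = geneSymbol(otx),
      description = otx@description,
      protein = prot)
  }
  if (is.na(regionAcc) && length(txResults))
    diags <- c(diags, list(diagnostic("info", "no_gene_region_record",
      "no gene-region (RefSeqGene-like) record is available for this locus; composed descriptions fall back to the chromosomal record")))

  new("ValidationReport", input = text, assembly = assembly, ok = TRUE,
      genomic = genomic, region = region, transcriptResults = txResults,
      diagnostics = diags)
}
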