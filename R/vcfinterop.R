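## Bit-exact conversion between genomic HGVS descriptions and VCF-style
## records.  VCF indels are LEFT-aligned (the opposite of the HGVS 3'-rule)
## and anchored with the preceding reference base; pseudo-VCF strings render
## the chromosome as the build's plain token (no "chr"), matching common
## aggregator identifiers.

#' Convert a genomic HGVS variant to a VCF-style tuple
#'
#' SNVs pass through; indels are left-aligned and anchored with the
#' preceding reference base (a variant at position 1 is anchored with the
#' following base instead).  c. variants must be projected to the genome
#' first.
#'
#' @param v a normalized g.-frame \linkS4class{ParsedVariant}
#' @param refset a \linkS4class{ReferenceSet}
#' @param assembly build label (defaults to the variant's hint, then the
#'   config default)
#' @return list(chrom = token, pos, ref, alt, assembly)
#' @export
hgvsGToVcf <- function(v, refset, assembly = NULL) {
  assembly <- assembly %||% v@assembly %||% refset@config$defaultAssembly
  if (is.na(assembly)) assembly <- refset@config$defaultAssembly
  if (v@coordType != "g")
    vsError("vs_not_genomic",
            "hgvsGToVcf needs a g. variant; project c./n. input first")
  acc <- resolveAccession(refset, v@accession, warnUnversioned = FALSE)
  if (is.na(acc))
    vsError("vs_unknown_reference",
            sprintf("cannot resolve reference %s", v@accession))
  context <- refset@sequences[[acc]]
  tok <- chromTokenForAccession(refset, assembly, acc)
  s <- v@start@base; e <- v@end@base

  anchored <- function(editStart, editEnd, insSeq) {
    ## deletion of [editStart..editEnd] or insertion of insSeq after
    ## editStart; left-align, then anchor
    if (is.null(insSeq)) {
      pe <- shuffle5(list(kind = "deletion", start = editStart,
                          end = editEnd, ref = "", alt = ""), context)
      if (pe$start > 1L)
        list(pos = pe$start - 1L,
             ref = substr(context, pe$start - 1L, pe$end),
             alt = substr(context, pe$start - 1L, pe$start - 1L))
      else  # deletion at position 1: anchor with the following base
        list(pos = 1L,
             ref = substr(context, pe$start, pe$end + 1L),
             alt = substr(context, pe$end + 1L, pe$end + 1L))
    } else {
      pe <- shuffle5(list(kind = "insertion", start = editStart,
                          end = editStart + 1L, ref = "", alt = insSeq),
                     context)
      if (pe$start >= 1L)
        list(pos = pe$start,
             ref = substr(context, pe$start, pe$start),
             alt = paste0(substr(context, pe$start, pe$start), pe$alt))
      else  # insertion before position 1: anchor with the following base
        list(pos = 1L,
             ref = substr(context, 1L, 1L),
             alt = paste0(pe$alt, substr(context, 1L, 1L)))
    }
  }

  rec <- switch(v@edit@kind,
    substitution = list(pos = s, ref = substr(context, s, s),
                        alt = v@edit@alt),
    identity = list(pos = s, ref = substr(context, s, s),
                    alt = substr(context, s, s)),
    deletion = anchored(s, e, NULL),
    duplication = anchored(e, NULL, substr(context, s, e)),
    insertion = anchored(s, NULL, v@edit@alt),
    delins = list(pos = s, ref = substr(context, s, e), alt = v@edit@alt),
    inversion = list(pos = s, ref = substr(context, s, e),
                     alt = revcomp(substr(context, s, e))),
    vsError("vs_unsupported_edit",
            paste0("cannot express edit kind ", v@edit@kind, " in VCF")))
  list(chrom = tok, pos = rec$pos, ref = rec$ref, alt = rec$alt,
       assembly = assembly)
}

#' Convert a VCF-style tuple to a normalized genomic HGVS variant
#'
#' Verifies REF against the reference sequence, minimizes the alleles, and
#' applies the HGVS 3'-rule; the inverse of \code{\link{hgvsGToVcf}} up to
#' normalization.
#'
#' @param tuple list/row with chrom, pos, ref, alt (chrom may be a token of
#'   \code{assembly} or an accession)
#' @param refset a \linkS4class{ReferenceSet}
#' @param assembly build label
#' @return a normalized g.-frame \linkS4class{ParsedVariant}
#' @export
vcfToHgvsG <- function(tuple, refset, assembly = NULL) {
  assembly <- assembly %||% tuple$assembly %||% refset@config$defaultAssembly
  acc <- chromAccessionForToken(as.character(tuple$chrom), assembly, refset)
  if (is.na(acc))
    vsError("vs_unknown_reference",
            sprintf("unknown chromosome token %s for assembly %s",
                    tuple$chrom, assembly))
  context <- refset@sequences[[acc]]
  pos <- as.integer(tuple$pos)
  ref <- toupper(tuple$ref); alt <- toupper(tuple$alt)
  found <- substr(context, pos, pos + nchar(ref) - 1L)
  if (found != ref)
    vsError("vs_ref_mismatch",
            sprintf("REF disagrees with %s at g.%d: stated %s, reference has %s",
                    acc, pos, ref, found))
  v <- new("ParsedVariant", accession = acc, coordType = "g",
           start = hgvsPosition(pos),
           end = hgvsPosition(pos + nchar(ref) - 1L),
           edit = if (ref == alt) edit_("identity", ref = ref)
                  else edit_("delins", ref = ref, alt = alt),
           assembly = assembly, inputKind = "pseudo_vcf_dash")
  normalizeVariant(v, refset, assembly)
}

#' Read a VCF file into VCF-style tuples
#'
#' Multi-allelic records are split into one tuple per ALT allele, input
#' order preserved.  Symbolic ALTs (\code{<DEL>}, breakends) are skipped
#' with a per-record warning.
#'
#' @param path VCF v4.x file
#' @param assembly build label attached to every tuple
#' @return list of list(chrom, pos, ref, alt, assembly); skipped records are
#'   reported via warnings
#' @export
readVcfTuples <- function(path, assembly = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  out <- list()
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (!grepl("^[ACGTNacgtn]+$", alt)) {  # symbolic ALT or breakend
        warning(sprintf("record %s:%s: symbolic ALT %s skipped",
                        fix[i, "CHROM"], fix[i, "POS"], alt), call. = FALSE)
        next
      }
      out[[length(out) + 1L]] <- list(
        chrom = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
        ref = unname(toupper(ref)), alt = unname(toupper(alt)),
        assembly = assembly)
    }
  }
  out
}

#' Render a genomic variant as a pseudo-VCF string
#'
#' \code{"<chromToken>-<pos>-<REF>-<ALT>"} built from
#' \code{\link{hgvsGToVcf}}; the form aggregation databases use as a variant
#' identifier.
#'
#' @inheritParams hgvsGToVcf
#' @return character scalar
#' @export
emitPseudoVcf <- function(v, refset, assembly = NULL) {
  t <- hgvsGToVcf(v, refset, assembly)
  paste(t$chrom, t$pos, t$ref, t$alt, sep = "-")
}
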