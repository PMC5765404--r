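#' @import methods
NULL

## Internal coordinate convention: all slots and exon tables are 0-based
## half-open interbase unless a name says otherwise; every user-facing HGVS
## position is 1-based inclusive.  Conversion happens at the load/format
## boundary only.

#' HGVS position with intronic offset and UTR context
#'
#' A single HGVS coordinate as printed in a c./n./g. description: a non-zero
#' base number (negative = 5'UTR for c.), an optional 3'UTR flag (star
#' positions, counted past the CDS end), and an intron offset (0 = exonic,
#' positive = downstream of an exon end, negative = upstream of an exon
#' start).  For g. positions \code{utr3} is always \code{FALSE} and
#' \code{offset} 0.
#'
#' @slot base non-zero integer position (1-based in its frame)
#' @slot utr3 logical; star position counted past the CDS end
#' @slot offset integer intron offset
#' @export
setClass("HgvsPosition",
  representation(base = "integer", utr3 = "logical", offset = "integer"),
  prototype(base = 1L, utr3 = FALSE, offset = 0L),
  validity = function(object) {
    if (length(object@base) != 1L || is.na(object@base))
      return("'base' must be a single non-NA integer")
    if (object@base == 0L) return("HGVS positions have no base 0")
    if (object@utr3 && object@base < 1L)
      return("3'UTR (star) positions require base >= 1")
    TRUE
  })

#' Construct an HgvsPosition
#'
#' @param base non-zero integer (negative = 5'UTR in the c. frame)
#' @param offset intron offset (default 0)
#' @param utr3 star (3'UTR) position?
#' @return an \linkS4class{HgvsPosition}
#' @export
hgvsPosition <- function(base, offset = 0L, utr3 = FALSE) {
  new("HgvsPosition", base = as.integer(base), offset = as.integer(offset),
      utr3 = isTRUE(utr3))
}

#' Algebraic description of a sequence change
#'
#' The edit part of a variant description, independent of coordinates:
#' substitution, deletion, duplication, insertion, deletion-insertion,
#' inversion, gene conversion (parse-only) or identity.  \code{ref} holds the
#' bases the description states were present (e.g. the "GTT" of delGTT);
#' \code{alt} the replacement/inserted bases.
#'
#' @slot kind one of substitution, deletion, duplication, insertion, delins,
#'   inversion, conversion, identity
#' @slot ref stated reference bases or NA
#' @slot alt alternate/inserted bases or NA
#' @slot conSource formatted source span of a conversion, or NA
#' @export
setClass("Edit",
  representation(kind = "character", ref = "character", alt = "character",
                 conSource = "character"),
  prototype(ref = NA_character_, alt = NA_character_,
            conSource = NA_character_),
  validity = function(object) {
    kinds <- c("substitution", "deletion", "duplication", "insertion",
               "delins", "inversion", "conversion", "identity")
    if (length(object@kind) != 1L || !(object@kind %in% kinds))
      return(paste0("'kind' must be one of: ", paste(kinds, collapse = ", ")))
    if (object@kind == "substitution" &&
        (is.na(object@ref) || nchar(object@ref) != 1L ||
         is.na(object@alt) || nchar(object@alt) != 1L))
      return("a substitution needs 1-base ref and alt")
    if (object@kind == "insertion" && (is.na(object@alt) || !nzchar(object@alt)))
      return("an insertion needs non-empty alt bases")
    if (object@kind == "delins" && (is.na(object@alt) || !nzchar(object@alt)))
      return("a delins needs non-empty alt bases")
    if (object@kind == "conversion" && is.na(object@conSource))
      return("a conversion carries its source span")
    TRUE
  })

#' Construct an Edit
#' @param kind edit kind (see \linkS4class{Edit})
#' @param ref stated reference bases (optional)
#' @param alt alternate bases (optional)
#' @param conSource conversion source span string (conversion only)
#' @return an \linkS4class{Edit}
#' @export
edit_ <- function(kind, ref = NA_character_, alt = NA_character_,
                  conSource = NA_character_) {
  new("Edit", kind = kind, ref = toupper(ref), alt = toupper(alt),
      conSource = conSource)
}

#' A parsed variant description
#'
#' The structured form of one input description: the reference context
#' (primary accession plus, for composed \code{NG_(NM_):c.} forms, the outer
#' genomic companion), the coordinate type, the interval, and the
#' \linkS4class{Edit}.  \code{inputKind} records which dialect the text was
#' written in; \code{assembly} carries a build hint from pseudo-VCF input.
#'
#' @slot accession primary reference identifier (or gene symbol / chromosome
#'   token for the styles that carry one)
#' @slot companion outer genomic accession of a composed description, or NA
#' @slot legacyCompanion legacy inner transcript designation
#'   (e.g. "GENE1_v003") seen instead of a real accession, or NA
#' @slot coordType one of g, c, n, p
#' @slot start,end \linkS4class{HgvsPosition} interval endpoints
#' @slot edit the \linkS4class{Edit}
#' @slot assembly build label hint (pseudo-VCF input), or NA
#' @slot inputKind one of hgvs, composed_hgvs, pseudo_vcf_dash,
#'   pseudo_vcf_colon, hybrid_hgvs_vcf, gene_symbol_style
#' @export
setClass("ParsedVariant",
  representation(accession = "character", companion = "character",
                 legacyCompanion = "character", coordType = "character",
                 start = "HgvsPosition", end = "HgvsPosition", edit = "Edit",
                 assembly = "character", inputKind = "character"),
  prototype(companion = NA_character_, legacyCompanion = NA_character_,
            assembly = NA_character_, inputKind = "hgvs"),
  validity = function(object) {
    if (!(object@coordType %in% c("g", "c", "n", "p")))
      return("coordType must be one of g, c, n, p")
    if (object@coordType == "g" &&
        (object@start@offset != 0L || object@start@base < 1L))
      return("g. positions have no offsets and start at 1")
    if (!is.na(object@companion) && !(object@coordType %in% c("c", "n")))
      return("composed descriptions only carry c. or n. coordinates")
    if (positionCompare(object@start, object@end) > 0L)
      return("interval start lies 3' of its end")
    TRUE
  })

#' A transcript alignment model
#'
#' One transcript: strand, per-assembly exon alignment blocks (with CIGAR
#' strings over M/I/D, where M may cover mismatching bases), CDS bounds, and
#' gene metadata.  Exon tables are interbase (0-based half-open) with columns
#' \code{tx_start,tx_end,g_start,g_end,cigar}, rows ordered 5'->3' in
#' transcript coordinates.
#'
#' @slot accession versioned transcript identifier
#' @slot geneSymbol,geneName current gene symbol and name
#' @slot strand "+" or "-" of the genomic alignment
#' @slot exons named list: assembly label -> list(chrom = chromosome
#'   accession, blocks = interbase exon data.frame)
#' @slot cds interbase CDS span \code{c(start, end)} on the transcript, or
#'   \code{integer(0)} for non-coding records
#' @slot description RefSeq-style definition line
#' @export
setClass("TranscriptRecord",
  representation(accession = "character", geneSymbol = "character",
                 geneName = "character", strand = "character",
                 exons = "list", cds = "integer", description = "character"),
  validity = function(object) {
    if (!(object@strand %in% c("+", "-"))) return("strand must be + or -")
    if (length(object@exons) == 0L) return("a transcript needs exon lists")
    txlen <- transcriptLength(object)
    for (asm in names(object@exons)) {
      b <- object@exons[[asm]]$blocks
      need <- c("tx_start", "tx_end", "g_start", "g_end", "cigar")
      if (!all(need %in% names(b)))
        return(paste0("exon table for ", asm, " lacks required columns"))
      if (nrow(b) > 1L) {
        if (any(diff(b$tx_start) <= 0) || any(b$tx_start[-1] < b$tx_end[-nrow(b)]))
          return("exon blocks must be ordered and non-overlapping in tx coords")
      }
      for (i in seq_len(nrow(b))) {
        cig <- cigarLengths(b$cigar[i])
        if (cig$tx != b$tx_end[i] - b$tx_start[i])
          return(paste0(object@accession, ": CIGAR tx length disagrees with ",
                        "tx_span in exon ", i, " (", asm, ")"))
        if (cig$g != b$g_end[i] - b$g_start[i])
          return(paste0(object@accession, ": CIGAR genomic length disagrees ",
                        "with g_span in exon ", i, " (", asm, ")"))
      }
      if (sum(b$tx_end - b$tx_start) != txlen)
        return("exon tx spans disagree across assemblies")
    }
    if (length(object@cds) == 2L) {
      if (object@cds[1] < 0L || object@cds[2] > txlen ||
          object@cds[1] >= object@cds[2])
        return("cds span must lie within the transcript")
    } else if (length(object@cds) != 0L) {
      return("cds must be integer(0) or length-2 interbase span")
    }
    TRUE
  })

#' The queryable reference universe
#'
#' Sequences, transcript models, gene-region (RefSeqGene-like) mappings,
#' cross-references (LRG/Ensembl-style aliases) and assembly chromosome maps,
#' loaded from a reference data bundle and cross-validated.
#'
#' @slot sequences named uppercase character vector, accession -> sequence
#' @slot moltype named character: accession -> chromosome / gene_region /
#'   transcript / protein
#' @slot seqDescriptions named character: accession -> definition line
#' @slot transcripts named list of \linkS4class{TranscriptRecord}
#' @slot regions named list of gene-region mappings: each
#'   \code{list(accession, chromosome = per-assembly accession, span =
#'   per-assembly interbase span, orientation, gene_symbol)}
#' @slot crossRefs data.frame with columns alias, target, sequence_identical
#' @slot assemblies named list: build label -> named character vector mapping
#'   chromosome token -> chromosome accession
#' @slot config prefix-map configuration list
#' @export
setClass("ReferenceSet",
  representation(sequences = "character", moltype = "character",
                 seqDescriptions = "character", transcripts = "list",
                 regions = "list", crossRefs = "data.frame",
                 assemblies = "list", config = "list"))

#' A validation diagnostic
#'
#' One message produced during validation: a severity, a stable
#' machine-readable code, human-readable text, and (for auto-corrections and
#' guidance) a suggested corrected input that is itself parseable.
#'
#' @slot severity error, warning or info
#' @slot code stable machine-readable identifier
#' @slot message human-readable text
#' @slot suggestion corrected/recommended description(s), or character(0)
#' @export
setClass("Diagnostic",
  representation(severity = "character", code = "character",
                 message = "character", suggestion = "character"),
  prototype(suggestion = character(0)),
  validity = function(object) {
    if (!(object@severity %in% c("error", "warning", "info")))
      return("severity must be error, warning or info")
    TRUE
  })

diagnostic <- function(severity, code, message, suggestion = character(0)) {
  new("Diagnostic", severity = severity, code = code, message = message,
      suggestion = suggestion)
}

#' A multi-context validation report
#'
#' The result of validating one description: the input echo and selected
#' assembly, genomic descriptions per build (HGVS, normalized form and
#' pseudo-VCF), a gene-region description when a RefSeqGene-like record
#' covers the locus, per-transcript descriptions (c./n., the composed
#' gene-region(transcript) or chromosome(transcript) form, transcript
#' definition line, gene symbol, protein prediction), and all diagnostics.
#' Any error diagnostic short-circuits the pipeline: the report then carries
#' diagnostics only (\code{ok == FALSE}).
#'
#' @slot input input description as submitted
#' @slot assembly selected build label
#' @slot ok logical; FALSE when an error diagnostic stopped the pipeline
#' @slot genomic named list per build: list(hgvs, normalized, pseudoVcf)
#' @slot region gene-region description list(accession, hgvs, normalized) or
#'   empty list
#' @slot transcriptResults list per overlapping transcript: list(accession,
#'   hgvs, normalized, composed, geneSymbol, description, protein)
#' @slot diagnostics list of \linkS4class{Diagnostic}
#' @export
setClass("ValidationReport",
  representation(input = "character", assembly = "character", ok = "logical",
                 genomic = "list", region = "list",
                 transcriptResults = "list", diagnostics = "list"),
  prototype(ok = TRUE, genomic = list(), region = list(),
            transcriptResults = list(), diagnostics = list()))
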