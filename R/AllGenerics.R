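#' @include AllClasses.R
NULL

#' Accession of a record
#' @param x a TranscriptRecord or ParsedVariant
#' @return character scalar
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))

#' @rdname accession
#' @export
setMethod("accession", "TranscriptRecord", function(x) x@accession)

#' @rdname accession
#' @export
setMethod("accession", "ParsedVariant", function(x) x@accession)

#' Gene symbol of a transcript record
#' @param x a TranscriptRecord
#' @return character scalar
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))

#' @rdname geneSymbol
#' @export
setMethod("geneSymbol", "TranscriptRecord", function(x) x@geneSymbol)

#' Strand of a transcript's genomic alignment
#' @param x a TranscriptRecord
#' @return "+" or "-"
#' @export
setGeneric("strand", function(x) standardGeneric("strand"))

#' @rdname strand
#' @export
setMethod("strand", "TranscriptRecord", function(x) x@strand)

#' Diagnostics attached to a validation report
#' @param x a ValidationReport
#' @return list of \linkS4class{Diagnostic}
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

#' @rdname diagnostics
#' @export
setMethod("diagnostics", "ValidationReport", function(x) x@diagnostics)

#' Severities / codes of diagnostics in a report
#' @param x a ValidationReport
#' @return character vector (possibly empty)
#' @export
diagnosticCodes <- function(x) {
  vapply(diagnostics(x), function(d) d@code, character(1))
}

#' @rdname diagnosticCodes
#' @export
diagnosticSeverities <- function(x) {
  vapply(diagnostics(x), function(d) d@severity, character(1))
}

#' Did validation complete without an error diagnostic?
#' @param x a ValidationReport
#' @return logical scalar
#' @export
isValid <- function(x) {
  stopifnot(is(x, "ValidationReport"))
  x@ok
}

#' Pseudo-VCF strings per build from a report
#' @param x a ValidationReport
#' @return named character vector, build label -> "CHROM-POS-REF-ALT"
#' @export
pseudoVcf <- function(x) {
  stopifnot(is(x, "ValidationReport"))
  vapply(x@genomic, function(g) g$pseudoVcf %||% NA_character_, character(1))
}

#' Genomic HGVS descriptions per build from a report
#' @param x a ValidationReport
#' @param normalized return the normalized (3'-shuffled) forms?
#' @return named character vector, build label -> description
#' @export
genomicDescriptions <- function(x, normalized = FALSE) {
  stopifnot(is(x, "ValidationReport"))
  field <- if (normalized) "normalized" else "hgvs"
  vapply(x@genomic, function(g) g[[field]] %||% NA_character_, character(1))
}

#' Per-transcript descriptions from a report
#' @param x a ValidationReport
#' @return named character vector, transcript accession -> c./n. description
#' @export
transcriptDescriptions <- function(x) {
  stopifnot(is(x, "ValidationReport"))
  out <- vapply(x@transcriptResults, function(t) t$hgvs, character(1))
  names(out) <- vapply(x@transcriptResults, function(t) t$accession, character(1))
  out
}

#' Protein predictions from a report
#' @param x a ValidationReport
#' @return named character vector, transcript accession -> p. description
#' @export
proteinPredictions <- function(x) {
  stopifnot(is(x, "ValidationReport"))
  keep <- !vapply(x@transcriptResults, function(t) is.null(t$protein), logical(1))
  out <- vapply(x@transcriptResults[keep], function(t) t$protein$label, character(1))
  names(out) <- vapply(x@transcriptResults[keep], function(t) t$accession,
                       character(1))
  out
}

setMethod("show", "HgvsPosition", function(object) {
  cat("HgvsPosition:", formatPosition(object), "\n")
})

setMethod("show", "Edit", function(object) {
  cat("Edit:", object@kind,
      if (!is.na(object@ref)) paste0("ref=", object@ref) else "",
      if (!is.na(object@alt)) paste0("alt=", object@alt) else "", "\n")
})

setMethod("show", "ParsedVariant", function(object) {
  cat("ParsedVariant <", object@inputKind, ">: ",
      formatVariant(object, style = "verbose_bases"), "\n", sep = "")
})

setMethod("show", "TranscriptRecord", function(object) {
  cds <- if (isCoding(object))
    sprintf("CDS tx %d..%d (1-based)", object@cds[1] + 1L, object@cds[2])
  else "non-coding"
  cat("TranscriptRecord ", object@accession, " (", object@geneSymbol,
      ", strand ", object@strand, ")\n  ", cds, "; ",
      nrow(object@exons[[1]]$blocks), " exon(s); assemblies: ",
      paste(names(object@exons), collapse = ", "), "\n  ",
      object@description, "\n", sep = "")
})

setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet: ", length(object@sequences), " sequences, ",
      length(object@transcripts), " transcripts, ",
      length(object@regions), " gene-region mapping(s), ",
      nrow(object@crossRefs), " cross-reference(s)\n  assemblies: ",
      paste(names(object@assemblies), collapse = ", "), "\n", sep = "")
})

setMethod("show", "Diagnostic", function(object) {
  cat("[", toupper(object@severity), " ", object@code, "] ", object@message,
      "\n", sep = "")
  for (s in object@suggestion) cat("    suggested: ", s, "\n", sep = "")
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport for \"", object@input, "\" (assembly ",
      object@assembly, ") -- ",
      if (object@ok) "validated" else "failed", "\n", sep = "")
  for (b in names(object@genomic)) {
    g <- object@genomic[[b]]
    cat("  ", b, ": ", g$hgvs, "  [", g$pseudoVcf, "]\n", sep = "")
  }
  if (length(object@region))
    cat("  gene region: ", object@region$hgvs, "\n", sep = "")
  for (t in object@transcriptResults) {
    cat("  ", t$hgvs, "  (", t$geneSymbol, ")",
        if (!is.null(t$protein)) paste0("  ", t$protein$label) else "",
        "\n", sep = "")
    cat("    ", t$composed, "\n", sep = "")
  }
  for (d in object@diagnostics) show(d)
})
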