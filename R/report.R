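## Report serialization: JSON (schema version 1) and a flat TSV.
## Diagnostics are always included; payloads carry no timestamps, so
## re-running a job is byte-for-byte deterministic.

diagAsList <- function(d) {
  list(severity = d@severity, code = d@code, message = d@message,
       suggestions = as.list(d@suggestion))
}

#' Convert a validation report to a plain list
#'
#' @param report a \linkS4class{ValidationReport}
#' @return a nested list mirroring the JSON schema (version 1)
#' @export
reportAsList <- function(report) {
  list(
    schema_version = 1L,
    input = report@input,
    assembly = report@assembly,
    ok = report@ok,
    genomic = report@genomic,
    gene_region = report@region,
    transcripts = lapply(unname(report@transcriptResults), function(t) {
      t$protein <- if (is.null(t$protein)) NULL else
        t$protein[c("kind", "label", "start_residue", "ref_aa", "alt_aa")]
      t
    }),
    diagnostics = lapply(report@diagnostics, diagAsList))
}

#' Serialize a validation report to JSON
#'
#' @param report a \linkS4class{ValidationReport}
#' @param pretty pretty-print?
#' @return a JSON string
#' @export
reportToJson <- function(report, pretty = TRUE) {
  as.character(jsonlite::toJSON(reportAsList(report), auto_unbox = TRUE,
                                null = "null", na = "null", pretty = pretty))
}

#' Serialize a validation report to a flat TSV
#'
#' One row per emitted description context plus one per diagnostic; columns
#' input, assembly, context, value, detail.
#'
#' @param report a \linkS4class{ValidationReport}
#' @return a data.frame (write with \code{write.table})
#' @export
reportToTsv <- function(report) {
  rows <- list()
  add <- function(context, value, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      input = report@input, assembly = report@assembly, context = context,
      value = value, detail = detail, stringsAsFactors = FALSE)
  }
  for (b in names(report@genomic)) {
    g <- report@genomic[[b]]
    add(paste0("genomic:", b), g$hgvs %||% "")
    if (!is.na(g$pseudoVcf %||% NA_character_))
      add(paste0("pseudo_vcf:", b), g$pseudoVcf)
  }
  if (length(report@region))
    add("gene_region", report@region$hgvs, report@region$accession)
  for (t in report@transcriptResults) {
    add(paste0("transcript:", t$accession), t$hgvs, t$geneSymbol)
    add(paste0("composed:", t$accession), t$composed)
    if (!is.null(t$protein))
      add(paste0("protein:", t$accession), t$protein$label, t$protein$kind)
  }
  for (d in report@diagnostics)
    add(paste0("diagnostic:", d@severity), d@code, d@message)
  if (!length(rows))
    return(data.frame(input = character(0), assembly = character(0),
                      context = character(0), value = character(0),
                      detail = character(0)))
  do.call(rbind, rows)
}
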