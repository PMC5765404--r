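## Protein consequence prediction by translate-and-diff: extract the CDS
## (the transcript sequence governs, never the genome -- this is what makes
## predictions robust to transcript-genome mismatches), apply the edit,
## translate both sequences with the standard code, and diff the proteins.
## Inversions are handled by applying the reverse complement in place, which
## the diff then classifies like any other change.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter", X = "Xaa")

aa3 <- function(aa) {
  paste(AA3[strsplit(aa, "")[[1]]], collapse = "")
}

#' Extract the coding sequence of a transcript
#'
#' Slices the transcript sequence (never the genome) to the CDS bounds.
#'
#' @param tx a coding \linkS4class{TranscriptRecord}
#' @param refset a \linkS4class{ReferenceSet}
#' @return nucleotide string starting at the initiator codon
#' @export
extractCds <- function(tx, refset) {
  if (!isCoding(tx))
    vsError("vs_noncoding",
            sprintf("%s is non-coding: no CDS to extract", tx@accession))
  substr(refset@sequences[[tx@accession]], tx@cds[1] + 1L, tx@cds[2])
}

#' Apply a CDS-frame edit to a coding sequence
#'
#' String surgery on the CDS: substitutions, deletions, duplications,
#' insertions and delins splice the sequence; an inversion replaces the
#' spanned bases by their reverse complement in place.
#'
#' @param cds coding sequence (position 1 = first base of the initiator)
#' @param v a c.-frame \linkS4class{ParsedVariant} fully within the CDS
#'   (exonic, no offsets, no UTR anchors)
#' @return the variant coding sequence
#' @export
applyEditToCds <- function(cds, v) {
  s <- v@start@base; e <- v@end@base
  if (v@start@offset != 0L || v@end@offset != 0L ||
      v@start@utr3 || v@end@utr3 || s < 1L || e > nchar(cds))
    vsError("vs_out_of_range", "edit is not fully within the CDS")
  pe <- switch(v@edit@kind,
    substitution = list(kind = "substitution", start = s, end = e,
                        alt = v@edit@alt),
    deletion = list(kind = "deletion", start = s, end = e),
    duplication = list(kind = "duplication", start = s, end = e),
    insertion = list(kind = "insertion", start = s, end = e, alt = v@edit@alt),
    delins = list(kind = "delins", start = s, end = e, alt = v@edit@alt),
    inversion = list(kind = "inversion", start = s, end = e),
    identity = list(kind = "identity", start = s, end = e),
    vsError("vs_unsupported_edit",
            paste0("cannot apply edit kind ", v@edit@kind, " to a CDS")))
  applyPositionedEdit(pe, cds)
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code; translation halts at the first stop codon
#' (rendered "*"); a trailing partial codon is ignored.
#'
#' @param nt nucleotide string (length >= 3)
#' @return amino-acid string in 1-letter code
#' @export
translateCds <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3L
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(nt, 3L * i - 2L, 3L * i)
    aa <- if (grepl("N", codon)) "X"
          else unname(Biostrings::GENETIC_CODE[codon])
    if (is.na(aa)) aa <- "X"
    out[i] <- aa
    if (aa == "*") return(paste(out[seq_len(i)], collapse = ""))
  }
  paste(out, collapse = "")
}

proteinVariant <- function(kind, label, startResidue = NA_integer_,
                           refAa = NA_character_, altAa = NA_character_,
                           fsStopDistance = NA_integer_) {
  list(kind = kind, label = label, start_residue = startResidue,
       ref_aa = refAa, alt_aa = altAa, fs_stop_distance = fsStopDistance,
       predicted = TRUE)
}

#' Diff two protein sequences into a predicted protein variant
#'
#' Trims the common prefix (and, where lengths permit, the common suffix)
#' and classifies the residue: no change with an underlying nucleotide
#' change is silent (p.(Xaa#=)); one residue for one is a substitution;
#' equal-length blocks are delins; in-frame gains/losses are
#' insertions/duplications/deletions (repeated residues named at their most
#' 3' position); a divergent tail with no shared suffix is a frameshift
#' named from the first changed residue, with the stop distance in the new
#' frame or "Ter?" when none is found; loss of the terminating codon is an
#' extension.  Output is always parenthesized: these are predictions.
#'
#' @param refAa,altAa amino-acid strings (1-letter, "*" = stop), both
#'   beginning at the initiator residue
#' @param affectedCodon 1-based codon index of the first nucleotide change
#'   (names the residue of a silent result)
#' @return a protein-variant list with elements kind, label, start_residue,
#'   ref_aa, alt_aa, fs_stop_distance, predicted
#' @export
diffProteins <- function(refAa, altAa, affectedCodon = NA_integer_) {
  if (identical(refAa, altAa)) {
    i <- if (is.na(affectedCodon)) 1L else min(affectedCodon, nchar(refAa))
    r <- substr(refAa, i, i)
    return(proteinVariant("silent", sprintf("p.(%s%d=)", AA3[[r]], i),
                          i, r, r))
  }
  a <- strsplit(refAa, "")[[1]]; b <- strsplit(altAa, "")[[1]]
  p <- 0L
  while (p < length(a) && p < length(b) && a[p + 1L] == b[p + 1L]) p <- p + 1L

  ## initiator disrupted: effect unpredictable
  if (p == 0L)
    return(proteinVariant("no_protein", "p.?"))

  ## stop lost: divergence begins at the reference stop; the protein is
  ## extended until the next stop in the new tail (if any)
  if (p < length(a) && a[p + 1L] == "*" && p < length(b) && b[p + 1L] != "*") {
    tail <- b[(p + 1L):length(b)]
    ext <- which(tail == "*")
    extPos <- if (length(ext)) ext[1] else NA_integer_
    return(proteinVariant(
      "extension",
      sprintf("p.(Ter%d%sext%s)", p + 1L, AA3[[tail[1]]],
              if (is.na(extPos)) "Ter?" else paste0("Ter", extPos)),
      p + 1L, "*", paste(tail, collapse = ""), extPos))
  }

  ## nonsense: the first divergent alternate residue is a stop
  if (p < length(b) && b[p + 1L] == "*" && p < length(a))
    return(proteinVariant(
      "substitution", sprintf("p.(%s%dTer)", AA3[[a[p + 1L]]], p + 1L),
      p + 1L, a[p + 1L], "*"))

  s <- 0L
  while (s < length(a) - p && s < length(b) - p &&
         a[length(a) - s] == b[length(b) - s]) s <- s + 1L
  refCore <- a[seq_len(length(a) - s)][-seq_len(p)]
  altCore <- b[seq_len(length(b) - s)][-seq_len(p)]

  ## frameshift: tails diverge with no shared suffix and different lengths
  if (s == 0L && length(refCore) != length(altCore) &&
      length(refCore) && length(altCore) &&
      !identical(refCore[length(refCore)], altCore[length(altCore)])) {
    i <- p + 1L
    stopAt <- which(altCore == "*")
    fsDist <- if (length(stopAt)) stopAt[1] else NA_integer_
    return(proteinVariant(
      "frameshift",
      sprintf("p.(%s%d%sfs%s)", AA3[[a[i]]], i, AA3[[altCore[1]]],
              if (is.na(fsDist)) "Ter?" else paste0("Ter", fsDist)),
      i, a[i], altCore[1], fsDist))
  }

  if (length(refCore) == 1L && length(altCore) == 1L)
    return(proteinVariant(
      "substitution",
      sprintf("p.(%s%d%s)", AA3[[refCore]], p + 1L, AA3[[altCore]]),
      p + 1L, refCore, altCore))

  if (length(altCore) == 0L) {
    ## deletion of refCore; report at the most 3' equivalent position
    del <- shiftRepeat3(a, p + 1L, p + length(refCore))
    lab <- if (del$start == del$end)
      sprintf("p.(%s%ddel)", AA3[[a[del$start]]], del$start)
    else
      sprintf("p.(%s%d_%s%ddel)", AA3[[a[del$start]]], del$start,
              AA3[[a[del$end]]], del$end)
    return(proteinVariant("deletion", lab, del$start,
                          paste(a[del$start:del$end], collapse = ""), ""))
  }

  if (length(refCore) == 0L) {
    ## insertion; duplication when it repeats the adjacent 5' residues
    ins <- altCore
    q <- p
    while (q + 1L <= length(a) && a[q + 1L] == ins[1]) {
      ins <- c(ins[-1], ins[1]); q <- q + 1L
    }
    k <- length(ins)
    if (q >= k && identical(a[(q - k + 1L):q], ins)) {
      lab <- if (k == 1L)
        sprintf("p.(%s%ddup)", AA3[[a[q]]], q)
      else
        sprintf("p.(%s%d_%s%ddup)", AA3[[a[q - k + 1L]]], q - k + 1L,
                AA3[[a[q]]], q)
      return(proteinVariant("duplication", lab, q - k + 1L,
                            paste(ins, collapse = ""), ""))
    }
    return(proteinVariant(
      "insertion",
      sprintf("p.(%s%d_%s%dins%s)", AA3[[a[q]]], q, AA3[[a[q + 1L]]], q + 1L,
              paste(AA3[ins], collapse = "")),
      q, "", paste(ins, collapse = "")))
  }

  ## equal-length (or residual) block replacement
  lab <- if (length(refCore) == 1L)
    sprintf("p.(%s%ddelins%s)", AA3[[refCore[1]]], p + 1L,
            paste(AA3[altCore], collapse = ""))
  else
    sprintf("p.(%s%d_%s%ddelins%s)", AA3[[refCore[1]]], p + 1L,
            AA3[[refCore[length(refCore)]]], p + length(refCore),
            paste(AA3[altCore], collapse = ""))
  proteinVariant("delins", lab, p + 1L,
                 paste(refCore, collapse = ""),
                 paste(altCore, collapse = ""))
}

## most 3' equivalent placement of a residue-block deletion
shiftRepeat3 <- function(a, i, j) {
  while (j + 1L <= length(a) && a[j + 1L] == a[i]) {
    i <- i + 1L; j <- j + 1L
  }
  list(start = i, end = j)
}

#' Predict the protein consequence of a transcript variant
#'
#' Orchestrates extract -> apply -> translate -> diff.  Intronic or
#' UTR-only variants yield a no-protein ("p.?") result, as do edits that
#' straddle a CDS boundary or disrupt the initiator codon.
#'
#' @param v a validated c.-frame \linkS4class{ParsedVariant} on \code{tx}
#' @param tx a coding \linkS4class{TranscriptRecord}
#' @param refset a \linkS4class{ReferenceSet}
#' @return a protein-variant list (see \code{\link{diffProteins}})
#' @export
predictProtein <- function(v, tx, refset) {
  if (v@coordType != "c" || !isCoding(tx))
    return(proteinVariant("no_protein", "p.?"))
  inCds <- function(pp) pp@offset == 0L && !pp@utr3 && pp@base >= 1L &&
    pp@base <= (tx@cds[2] - tx@cds[1])
  if (!inCds(v@start) || !inCds(v@end)) {
    ## fully outside the CDS -> no protein effect is predicted
    return(proteinVariant("no_protein", "p.?"))
  }
  cds <- extractCds(tx, refset)
  altCds <- applyEditToCds(cds, v)
  refAa <- translateCds(cds)
  altAa <- translateCds(altCds)
  diffProteins(refAa, altAa, affectedCodon = (v@start@base - 1L) %/% 3L + 1L)
}
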