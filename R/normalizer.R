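## Canonicalization of edits: trim raw ref/alt pairs to minimal form, shuffle
## indels to the maximal 3' position of the reported reference (the HGVS
## 3'-rule; the opposite convention to VCF left-alignment), and re-classify
## shuffled insertions as duplications when they exactly repeat the adjacent
## 5' sequence.  c./n.-frame normalization operates on the genome-backed
## pre-mRNA sequence in transcript orientation, so a shuffle may carry an
## edit across an exon/intron junction and the result is expressed with
## intronic offsets.
##
## Positioned edits are plain lists: list(kind, start, end, ref, alt) with
## 1-based inclusive coordinates on a context string.  An insertion sits
## between `start` and `end` = start + 1 (start may be 0 at the 5' edge).

rotL <- function(s) paste0(substr(s, 2L, nchar(s)), substr(s, 1L, 1L))
rotR <- function(s) paste0(substr(s, nchar(s), nchar(s)),
                           substr(s, 1L, nchar(s) - 1L))

#' Trim a raw ref/alt triple to its minimal positioned edit
#'
#' Removes the longest common prefix, then the longest common suffix, of the
#' stated ref and alt alleles and classifies the residue: 1<->1 base is a
#' substitution, k<->0 a deletion, 0<->k an insertion, k<->m a delins.  An
#' identical pair yields an identity result (callers warn).
#'
#' @param pos 1-based anchor position of \code{ref} on the reference
#' @param ref,alt allele strings over A/C/G/T/N
#' @return list(kind, start, end, ref, alt); for an insertion \code{start} is
#'   the 5'-flanking position and \code{end = start + 1}
#' @export
minimizeTriple <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  a <- strsplit(ref, "")[[1]]; b <- strsplit(alt, "")[[1]]
  p <- 0L
  while (p < length(a) && p < length(b) && a[p + 1L] == b[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < length(a) - p && s < length(b) - p &&
         a[length(a) - s] == b[length(b) - s]) s <- s + 1L
  refCore <- if (length(a) - s >= p + 1L)
    paste(a[(p + 1L):(length(a) - s)], collapse = "") else ""
  altCore <- if (length(b) - s >= p + 1L)
    paste(b[(p + 1L):(length(b) - s)], collapse = "") else ""
  start <- pos + p
  la <- nchar(refCore); lb <- nchar(altCore)
  if (la == 0L && lb == 0L)
    list(kind = "identity", start = pos, end = pos + nchar(ref) - 1L,
         ref = ref, alt = alt)
  else if (la == 1L && lb == 1L)
    list(kind = "substitution", start = start, end = start,
         ref = refCore, alt = altCore)
  else if (lb == 0L)
    list(kind = "deletion", start = start, end = start + la - 1L,
         ref = refCore, alt = "")
  else if (la == 0L)
    list(kind = "insertion", start = start - 1L, end = start,
         ref = "", alt = altCore)
  else
    list(kind = "delins", start = start, end = start + la - 1L,
         ref = refCore, alt = altCore)
}

#' Slide an indel to its maximal 3' position
#'
#' Rotate-and-advance over repeats: the edit is slid toward the 3' end of the
#' context (read 5'->3' in the orientation of the reported reference) for as
#' long as the produced edited sequence is unchanged.  N bases never match.
#' Deletions and duplications shift their interval; insertions shift their
#' flanking point and rotate the inserted bases.
#'
#' @param edit positioned edit (see \code{\link{minimizeTriple}})
#' @param context reference sequence the positions refer to
#' @return the repositioned edit, with \code{ref} refreshed from the context
#'   for deletions/duplications
#' @export
shuffle3 <- function(edit, context) {
  n <- nchar(context)
  ch <- function(i) substr(context, i, i)
  if (edit$kind %in% c("deletion", "duplication")) {
    i <- edit$start; j <- edit$end
    while (j + 1L <= n && ch(j + 1L) == ch(i) && ch(i) != "N") {
      i <- i + 1L; j <- j + 1L
    }
    edit$start <- i; edit$end <- j
    edit$ref <- substr(context, i, j)
  } else if (edit$kind == "insertion") {
    p <- edit$start; s <- edit$alt
    while (p + 1L <= n && ch(p + 1L) == substr(s, 1L, 1L) &&
           substr(s, 1L, 1L) != "N") {
      s <- rotL(s); p <- p + 1L
    }
    edit$start <- p; edit$end <- p + 1L; edit$alt <- s
  }
  edit
}

## mirror of shuffle3: maximal 5' position (VCF left alignment)
shuffle5 <- function(edit, context) {
  ch <- function(i) substr(context, i, i)
  if (edit$kind %in% c("deletion", "duplication")) {
    i <- edit$start; j <- edit$end
    while (i - 1L >= 1L && ch(i - 1L) == ch(j) && ch(j) != "N") {
      i <- i - 1L; j <- j - 1L
    }
    edit$start <- i; edit$end <- j
    edit$ref <- substr(context, i, j)
  } else if (edit$kind == "insertion") {
    p <- edit$start; s <- edit$alt
    last <- function(x) substr(x, nchar(x), nchar(x))
    while (p >= 1L && ch(p) == last(s) && last(s) != "N") {
      s <- rotR(s); p <- p - 1L
    }
    edit$start <- p; edit$end <- p + 1L; edit$alt <- s
  }
  edit
}

## after a 3' shuffle, an insertion that exactly repeats the adjacent 5'
## sequence is a duplication (full-length match only; partial repeats stay
## insertions)
dupDetect <- function(edit, context) {
  if (edit$kind != "insertion") return(edit)
  k <- nchar(edit$alt); p <- edit$start
  if (p >= k && substr(context, p - k + 1L, p) == edit$alt)
    list(kind = "duplication", start = p - k + 1L, end = p,
         ref = edit$alt, alt = "")
  else edit
}

## apply a positioned edit to its context (internal; test oracles re-derive
## this independently)
applyPositionedEdit <- function(edit, context) {
  switch(edit$kind,
    identity = context,
    substitution = spliceSeq(context, edit$start, edit$end, edit$alt),
    deletion = spliceSeq(context, edit$start, edit$end, ""),
    delins = spliceSeq(context, edit$start, edit$end, edit$alt),
    insertion = spliceSeq(context, edit$start + 1L, edit$start, edit$alt),
    duplication = spliceSeq(context, edit$end + 1L, edit$end,
                            substr(context, edit$start, edit$end)),
    inversion = spliceSeq(context, edit$start, edit$end,
                          revcomp(substr(context, edit$start, edit$end))),
    stop("cannot apply edit kind ", edit$kind))
}

## ParsedVariant -> positioned edit on a context, given index functions
asPositionedEdit <- function(v, i1, i2, context) {
  e <- v@edit
  if (e@kind == "insertion")
    list(kind = "insertion", start = i1, end = i1 + 1L, ref = "", alt = e@alt)
  else
    list(kind = e@kind, start = i1, end = i2,
         ref = if (!is.na(e@ref)) e@ref else substr(context, i1, i2),
         alt = if (!is.na(e@alt)) e@alt else "")
}

#' Normalize a variant description
#'
#' Minimizes raw ref/alt pairs (hybrid HGVS:VCF and delins input), applies
#' the HGVS 3'-rule in the orientation of the reported reference, and
#' re-classifies insertions as duplications where appropriate.  g. variants
#' normalize on the chromosome's forward sense; c./n. variants normalize on
#' the genome-backed pre-mRNA in transcript orientation (minus-strand genes
#' therefore shuffle toward genomic 5'), so edits may cross an exon/intron
#' junction and gain intronic offsets.  Stated reference bases are re-read
#' from the governing sequence.  Substitutions, inversions and conversions
#' normalize to themselves.
#'
#' @param v a validated \linkS4class{ParsedVariant}
#' @param refset a \linkS4class{ReferenceSet}
#' @param assembly build label (defaults to the variant's hint, then the
#'   config default)
#' @return a \linkS4class{ParsedVariant}
#' @export
normalizeVariant <- function(v, refset, assembly = NULL) {
  assembly <- assembly %||% v@assembly %||% refset@config$defaultAssembly
  if (is.na(assembly)) assembly <- refset@config$defaultAssembly
  if (v@edit@kind %in% c("conversion", "inversion")) return(v)

  if (v@coordType == "g") {
    acc <- resolveAccession(refset, v@accession, warnUnversioned = FALSE)
    if (is.na(acc)) acc <- chromAccessionForToken(v@accession, assembly, refset)
    if (is.na(acc))
      vsError("vs_unknown_reference",
              sprintf("cannot resolve reference %s", v@accession))
    context <- refset@sequences[[acc]]
    pe <- asPositionedEdit(v, v@start@base, v@end@base, context)
    pe <- normalizePositioned(pe, context)
    out <- positionedToGenomicVariant(pe, acc, v, context)
    out@assembly <- if (!is.na(v@assembly)) v@assembly else assembly
    return(out)
  }

  ## c./n. frame: normalize on the oriented, genome-backed pre-mRNA
  res <- resolveReference(refset, v@accession)
  if (res$type != "transcript")
    vsError("vs_no_path",
            sprintf("%s. normalization needs a transcript record (got %s)",
                    v@coordType, res$type))
  tx <- res$record
  txAsm <- if (assembly %in% names(tx@exons)) assembly else names(tx@exons)[1L]
  ctx <- premrnaContext(tx, txAsm, refset)
  n1 <- toTxFrame(v@start, v, tx); n2 <- toTxFrame(v@end, v, tx)
  i1 <- nPosToCtxIndex(n1, tx, txAsm, ctx)
  i2 <- nPosToCtxIndex(n2, tx, txAsm, ctx)
  pe <- asPositionedEdit(v, i1, i2, ctx$seq)
  pe <- normalizePositioned(pe, ctx$seq)

  idx2n <- function(i) genomicToTx(ctxIndexToG(ctx, i), tx, txAsm)
  if (pe$kind == "insertion") {
    s <- idx2n(pe$start); e <- idx2n(pe$end)
  } else {
    s <- idx2n(pe$start); e <- idx2n(pe$end)
  }
  ref <- if (pe$kind %in% c("deletion", "duplication", "identity"))
    governingBases(s, e, tx, txAsm, refset) else NA_character_
  alt <- switch(pe$kind,
                substitution = pe$alt, insertion = pe$alt, delins = pe$alt,
                NA_character_)
  if (pe$kind == "substitution")
    ref <- governingBases(s, s, tx, txAsm, refset)
  if (pe$kind == "delins")
    ref <- governingBases(s, e, tx, txAsm, refset)
  new("ParsedVariant", accession = v@accession, companion = v@companion,
      coordType = v@coordType,
      start = fromTxFrame(s, v@coordType, tx),
      end = fromTxFrame(e, v@coordType, tx),
      edit = edit_(pe$kind, ref = ref, alt = alt),
      assembly = v@assembly, inputKind = v@inputKind)
}

## shared minimize -> shuffle -> dup-detect pipeline on a positioned edit
normalizePositioned <- function(pe, context) {
  if (pe$kind %in% c("delins", "substitution") ||
      (pe$kind == "identity" && nzchar(pe$alt))) {
    pe <- minimizeTriple(pe$start, pe$ref, pe$alt)
  }
  if (pe$kind %in% c("deletion", "duplication", "insertion")) {
    pe <- shuffle3(pe, context)
    pe <- dupDetect(pe, context)
  }
  pe
}

positionedToGenomicVariant <- function(pe, acc, v, context) {
  if (pe$kind == "insertion") {
    start <- hgvsPosition(pe$start); end <- hgvsPosition(pe$end)
    ed <- edit_("insertion", alt = pe$alt)
  } else if (pe$kind == "identity") {
    start <- hgvsPosition(pe$start); end <- hgvsPosition(pe$end)
    ed <- edit_("identity", ref = substr(context, pe$start, pe$end))
  } else {
    start <- hgvsPosition(pe$start); end <- hgvsPosition(pe$end)
    ed <- edit_(pe$kind,
                ref = if (nzchar(pe$ref)) pe$ref
                      else substr(context, pe$start, pe$end),
                alt = if (pe$kind %in% c("substitution", "delins")) pe$alt
                      else NA_character_)
  }
  new("ParsedVariant", accession = acc, coordType = "g",
      start = start, end = end, edit = ed,
      assembly = v@assembly, inputKind = v@inputKind)
}
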