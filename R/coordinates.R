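## Exact projection between CDS, transcript, chromosome, gene-region and
## second-assembly frames.  All arithmetic walks the exon alignment CIGARs,
## so transcript-genome indel discrepancies (I/D ops) are detected and
## refused rather than silently shifted through.

vsError <- function(class, msg) {
  stop(structure(class = c(class, "vs_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

exonSet <- function(tx, assembly) {
  ex <- tx@exons[[assembly]]
  if (is.null(ex))
    vsError("vs_no_path",
            sprintf("transcript %s is not mapped to assembly %s (available: %s)",
                    tx@accession, assembly,
                    paste(names(tx@exons), collapse = ", ")))
  ex
}

#' CDS-relative to transcript-relative coordinate
#'
#' Relates a c. position to its n. position: body positions count from the
#' CDS start, negative positions reach into the 5'UTR (there is no position
#' zero), and star positions count past the CDS end.  The intron offset
#' passes through unchanged.
#'
#' @param pos an \linkS4class{HgvsPosition} in the c. frame
#' @param tx a coding \linkS4class{TranscriptRecord}
#' @return an \linkS4class{HgvsPosition} in the n. frame
#' @export
cdsToTx <- function(pos, tx) {
  if (!isCoding(tx))
    vsError("vs_noncoding",
            sprintf("%s is non-coding: c. positions are undefined (use n.)",
                    tx@accession))
  cdsStart1 <- tx@cds[1] + 1L
  cdsEnd1 <- tx@cds[2]
  n <- if (pos@utr3) cdsEnd1 + pos@base
       else if (pos@base >= 1L) cdsStart1 + pos@base - 1L
       else cdsStart1 + pos@base
  if (n < 1L || n > transcriptLength(tx))
    vsError("vs_out_of_range",
            sprintf("c.%s lies outside transcript %s (length %d)",
                    formatPosition(pos), tx@accession, transcriptLength(tx)))
  hgvsPosition(n, pos@offset)
}

#' Transcript-relative to CDS-relative coordinate
#'
#' @param pos an \linkS4class{HgvsPosition} in the n. frame
#' @param tx a coding \linkS4class{TranscriptRecord}
#' @return an \linkS4class{HgvsPosition} in the c. frame
#' @export
txToCds <- function(pos, tx) {
  if (!isCoding(tx))
    vsError("vs_noncoding",
            sprintf("%s is non-coding: c. positions are undefined", tx@accession))
  cdsStart1 <- tx@cds[1] + 1L
  cdsEnd1 <- tx@cds[2]
  n <- pos@base
  if (n < cdsStart1) hgvsPosition(n - cdsStart1, pos@offset)
  else if (n > cdsEnd1) hgvsPosition(n - cdsEnd1, pos@offset, utr3 = TRUE)
  else hgvsPosition(n - cdsStart1 + 1L, pos@offset)
}

## exonic transcript base (1-based n, offset 0) -> 1-based genomic position
exonicTxToG <- function(tx, assembly, n) {
  ex <- exonSet(tx, assembly)
  b <- ex$blocks
  tx0 <- n - 1L
  i <- which(b$tx_start <= tx0 & tx0 < b$tx_end)
  if (!length(i))
    vsError("vs_out_of_range",
            sprintf("n.%d lies outside transcript %s", n, tx@accession))
  i <- i[1L]
  co <- cigarOps(b$cigar[i])
  txc <- 0L; gc <- 0L
  want <- tx0 - b$tx_start[i]
  for (k in seq_along(co$op)) {
    op <- co$op[k]; len <- co$len[k]
    if (op == "M") {
      if (want < txc + len) {
        goff <- gc + (want - txc)
        return(if (tx@strand == "+") b$g_start[i] + goff + 1L
               else b$g_end[i] - goff)
      }
      txc <- txc + len; gc <- gc + len
    } else if (op == "I") {
      if (want < txc + len)
        vsError("vs_no_genomic_counterpart",
                sprintf("n.%d of %s falls in a transcript-only insertion and has no genomic counterpart",
                        n, tx@accession))
      txc <- txc + len
    } else gc <- gc + len
  }
  vsError("vs_out_of_range", "CIGAR walk exhausted")  # unreachable if valid
}

## intron length (bases) between exon blocks i and i+1, in transcript order
intronLength <- function(tx, assembly, i) {
  b <- exonSet(tx, assembly)$blocks
  if (tx@strand == "+") b$g_start[i + 1L] - b$g_end[i]
  else b$g_start[i] - b$g_end[i + 1L]
}

## which exon block holds transcript base n; plus boundary flags
blockOf <- function(tx, assembly, n) {
  b <- exonSet(tx, assembly)$blocks
  tx0 <- n - 1L
  i <- which(b$tx_start <= tx0 & tx0 < b$tx_end)[1L]
  if (is.na(i))
    vsError("vs_out_of_range",
            sprintf("n.%d lies outside transcript %s", n, tx@accession))
  list(i = i, first = tx0 == b$tx_start[i], last = tx0 == b$tx_end[i] - 1L,
       n = nrow(b))
}

#' Transcript to genomic coordinate
#'
#' Maps an n.-frame position (with optional intron offset) through the exon
#' alignment CIGARs of one assembly.  A positive offset walks into the intron
#' 3' of the anchor base in transcript orientation (so plus-strand genes add
#' the offset on the genome and minus-strand genes subtract it); a negative
#' offset walks 5'.  With \code{strict = TRUE} (default) a nonzero offset is
#' only accepted on a true exon-boundary base in the offset's direction --
#' the condition the validator's boundary auto-correction detects.
#'
#' @param pos \linkS4class{HgvsPosition}, n. frame
#' @param tx a \linkS4class{TranscriptRecord}
#' @param assembly build label
#' @param strict enforce exon-boundary anchoring of intronic offsets
#' @return list(chrom = chromosome accession, pos = 1-based genomic position)
#' @export
txToGenomic <- function(pos, tx, assembly, strict = TRUE) {
  ex <- exonSet(tx, assembly)
  g1 <- exonicTxToG(tx, assembly, pos@base)
  if (pos@offset == 0L) return(list(chrom = ex$chrom, pos = g1))
  blk <- blockOf(tx, assembly, pos@base)
  if (strict) {
    if (pos@offset > 0L) {
      if (!blk$last || blk$i == blk$n)
        vsError("vs_nonboundary_offset",
                sprintf("n.%d is not the last base of a non-terminal exon of %s; +%d offset is invalid",
                        pos@base, tx@accession, pos@offset))
      if (pos@offset > intronLength(tx, assembly, blk$i))
        vsError("vs_offset_exceeds_intron",
                sprintf("offset +%d exceeds the %d-base intron after n.%d of %s",
                        pos@offset, intronLength(tx, assembly, blk$i),
                        pos@base, tx@accession))
    } else {
      if (!blk$first || blk$i == 1L)
        vsError("vs_nonboundary_offset",
                sprintf("n.%d is not the first base of a non-initial exon of %s; %d offset is invalid",
                        pos@base, tx@accession, pos@offset))
      if (-pos@offset > intronLength(tx, assembly, blk$i - 1L))
        vsError("vs_offset_exceeds_intron",
                sprintf("offset %d exceeds the %d-base intron before n.%d of %s",
                        pos@offset, intronLength(tx, assembly, blk$i - 1L),
                        pos@base, tx@accession))
    }
  }
  g <- if (tx@strand == "+") g1 + pos@offset else g1 - pos@offset
  list(chrom = ex$chrom, pos = g)
}

#' Genomic to transcript coordinate
#'
#' Inverse of \code{\link{txToGenomic}}.  Exonic positions return offset 0;
#' intronic positions anchor to the nearer exon boundary (ties break to the
#' \code{+} offset from the preceding exon); positions outside the
#' transcript's genomic footprint raise an error, as do positions falling in
#' a genome-only (D) alignment gap.
#'
#' @param gpos 1-based genomic position on the transcript's chromosome
#' @param tx a \linkS4class{TranscriptRecord}
#' @param assembly build label
#' @return \linkS4class{HgvsPosition} in the n. frame
#' @export
genomicToTx <- function(gpos, tx, assembly) {
  ex <- exonSet(tx, assembly)
  b <- ex$blocks
  g0 <- gpos - 1L
  fp <- txFootprint(tx, assembly)
  if (g0 < fp$span[1] || g0 >= fp$span[2])
    vsError("vs_out_of_footprint",
            sprintf("g.%d is not within transcript %s (footprint g.%d-%d)",
                    gpos, tx@accession, fp$span[1] + 1L, fp$span[2]))
  for (i in seq_len(nrow(b))) {
    if (b$g_start[i] <= g0 && g0 < b$g_end[i]) {
      goff <- if (tx@strand == "+") g0 - b$g_start[i] else b$g_end[i] - 1L - g0
      co <- cigarOps(b$cigar[i])
      txc <- 0L; gc <- 0L
      for (k in seq_along(co$op)) {
        op <- co$op[k]; len <- co$len[k]
        if (op == "M") {
          if (goff < gc + len)
            return(hgvsPosition(b$tx_start[i] + txc + (goff - gc) + 1L))
          txc <- txc + len; gc <- gc + len
        } else if (op == "D") {
          if (goff < gc + len)
            vsError("vs_no_transcript_counterpart",
                    sprintf("g.%d of %s falls in a genome-only alignment gap of %s",
                            gpos, ex$chrom, tx@accession))
          gc <- gc + len
        } else txc <- txc + len
      }
    }
  }
  ## intronic: find flanking exons in transcript order
  for (i in seq_len(nrow(b) - 1L)) {
    inIntron <- if (tx@strand == "+")
      b$g_end[i] <= g0 && g0 < b$g_start[i + 1L]
    else
      b$g_end[i + 1L] <= g0 && g0 < b$g_start[i]
    if (inIntron) {
      if (tx@strand == "+") {
        dPrec <- gpos - b$g_end[i]                 # from last base of exon i
        dFoll <- b$g_start[i + 1L] + 1L - gpos     # to first base of exon i+1
      } else {
        dPrec <- b$g_start[i] + 1L - gpos
        dFoll <- gpos - b$g_end[i + 1L]
      }
      return(if (dPrec <= dFoll) hgvsPosition(b$tx_end[i], dPrec)
             else hgvsPosition(b$tx_start[i + 1L] + 1L, -dFoll))
    }
  }
  vsError("vs_out_of_footprint",
          sprintf("g.%d is not within transcript %s", gpos, tx@accession))
}

## position in the frame the variant's coordType uses -> n. frame
toTxFrame <- function(pos, v, tx) {
  if (v@coordType == "c") cdsToTx(pos, tx) else pos
}
fromTxFrame <- function(pos, coordType, tx) {
  if (coordType == "c") txToCds(pos, tx) else pos
}

## ------------------------------------------------------------------------
## pre-mRNA context: genome-backed sequence in transcript orientation,
## spanning the genomic footprint, with index <-> coordinate maps.  Used by
## c./n.-frame normalization and by governing-sequence reads.
premrnaContext <- function(tx, assembly, refset) {
  ex <- exonSet(tx, assembly)
  fp <- txFootprint(tx, assembly)
  chromSeq <- refset@sequences[[ex$chrom]]
  ctx <- seqSlice(chromSeq, fp$span[1] + 1L, fp$span[2], what = ex$chrom)
  if (tx@strand == "-") ctx <- revcomp(ctx)
  list(seq = ctx, chrom = ex$chrom, span1 = fp$span[1] + 1L,
       span2 = fp$span[2], strand = tx@strand)
}

ctxIndexToG <- function(ctx, i) {
  if (ctx$strand == "+") ctx$span1 + i - 1L else ctx$span2 - i + 1L
}
gToCtxIndex <- function(ctx, g1) {
  if (ctx$strand == "+") g1 - ctx$span1 + 1L else ctx$span2 - g1 + 1L
}

## n-frame position (with offset) -> pre-mRNA context index
nPosToCtxIndex <- function(pos, tx, assembly, ctx) {
  g <- txToGenomic(pos, tx, assembly, strict = FALSE)
  gToCtxIndex(ctx, g$pos)
}

## bases of the governing sequence over an n-frame interval: transcript bases
## for exonic positions, (oriented) genomic bases for intronic ones
governingBases <- function(startPos, endPos, tx, assembly, refset) {
  ctx <- premrnaContext(tx, assembly, refset)
  i1 <- nPosToCtxIndex(startPos, tx, assembly, ctx)
  i2 <- nPosToCtxIndex(endPos, tx, assembly, ctx)
  txSeq <- refset@sequences[[tx@accession]]
  out <- character(i2 - i1 + 1L)
  for (i in seq(i1, i2)) {
    g1 <- ctxIndexToG(ctx, i)
    np <- tryCatch(genomicToTx(g1, tx, assembly), error = function(e) NULL)
    out[i - i1 + 1L] <-
      if (!is.null(np) && np@offset == 0L) substr(txSeq, np@base, np@base)
      else substr(ctx$seq, i, i)
  }
  paste(out, collapse = "")
}

## ------------------------------------------------------------------------
## variant projection

frameOf <- function(v, refset) {
  if (v@coordType %in% c("c", "n")) {
    res <- resolveReference(refset, v@accession)
    if (res$type != "transcript")
      vsError("vs_no_path",
              sprintf("%s is not a transcript record; %s. coordinates need one",
                      v@accession, v@coordType))
    list(type = "transcript", tx = res$record)
  } else {
    acc <- resolveAccession(refset, v@accession, warnUnversioned = FALSE)
    if (is.na(acc))
      vsError("vs_unknown_reference",
              sprintf("cannot resolve reference %s", v@accession))
    mt <- refset@moltype[[acc]]
    list(type = mt, accession = acc)
  }
}

## assembly that publishes a chromosome accession
assemblyOfChromosome <- function(refset, acc) {
  for (a in names(refset@assemblies))
    if (acc %in% refset@assemblies[[a]]) return(a)
  NA_character_
}

reviseEdit <- function(e, refSeq, flip) {
  ref <- e@ref; alt <- e@alt
  if (flip) {
    if (!is.na(alt)) alt <- revcomp(alt)
    if (!is.na(ref)) ref <- revcomp(ref)
  }
  if (!is.null(refSeq)) ref <- refSeq  # re-read from the target sequence
  if (e@kind == "substitution") edit_("substitution", ref, alt)
  else edit_(e@kind, ref = ref, alt = alt, conSource = e@conSource)
}

## stated-reference slice of a genomic variant on its chromosome
genomicRefSlice <- function(refset, chrom, start1, end1) {
  seqSlice(refset@sequences[[chrom]], start1, end1, what = chrom)
}

## project a validated variant to genomic coordinates on `assembly`.
## Returns a g-frame ParsedVariant on that assembly's chromosome.
variantToGenomic <- function(v, refset, assembly) {
  fr <- frameOf(v, refset)
  if (fr$type == "transcript") {
    tx <- fr$tx
    p1 <- txToGenomic(toTxFrame(v@start, v, tx), tx, assembly, strict = FALSE)
    p2 <- txToGenomic(toTxFrame(v@end, v, tx), tx, assembly, strict = FALSE)
    flip <- tx@strand == "-"
    gstart <- min(p1$pos, p2$pos); gend <- max(p1$pos, p2$pos)
    refSeq <- if (v@edit@kind %in%
                  c("deletion", "duplication", "inversion", "identity"))
      genomicRefSlice(refset, p1$chrom, gstart, gend)
    else if (v@edit@kind == "substitution")
      genomicRefSlice(refset, p1$chrom, gstart, gstart)
    else NULL
    new("ParsedVariant", accession = p1$chrom, coordType = "g",
        start = hgvsPosition(gstart), end = hgvsPosition(gend),
        edit = reviseEdit(v@edit, refSeq, flip),
        assembly = assembly, inputKind = v@inputKind)
  } else if (fr$type == "chromosome") {
    srcAsm <- assemblyOfChromosome(refset, fr$accession)
    vv <- v
    vv@accession <- fr$accession
    vv@assembly <- srcAsm
    if (identical(srcAsm, assembly)) return(vv)
    crossBuildGenomic(vv, refset, assembly)
  } else if (fr$type == "gene_region") {
    regionToChromosome(v, refset, fr$accession, assembly)
  } else {
    vsError("vs_no_path",
            sprintf("no projection path from a %s record to assembly %s",
                    fr$type, assembly))
  }
}

## g. on a gene-region record -> g. on the chromosome of `assembly`
regionToChromosome <- function(v, refset, acc, assembly) {
  reg <- refset@regions[[acc]]
  if (is.null(reg) || !(assembly %in% names(reg$span)))
    vsError("vs_no_path",
            sprintf("gene region %s has no mapping to assembly %s", acc,
                    assembly))
  span <- reg$span[[assembly]]
  chrom <- reg$chromosome[[assembly]]
  flip <- reg$orientation == "-"
  mapPos <- function(p) {
    if (!flip) span[1] + p@base else span[2] - p@base + 1L
  }
  g1 <- mapPos(v@start); g2 <- mapPos(v@end)
  gstart <- min(g1, g2); gend <- max(g1, g2)
  refSeq <- if (v@edit@kind %in%
                c("deletion", "duplication", "inversion", "identity"))
    genomicRefSlice(refset, chrom, gstart, gend)
  else if (v@edit@kind == "substitution")
    genomicRefSlice(refset, chrom, gstart, gstart)
  else NULL
  new("ParsedVariant", accession = chrom, coordType = "g",
      start = hgvsPosition(gstart), end = hgvsPosition(gend),
      edit = reviseEdit(v@edit, refSeq, flip),
      assembly = assembly, inputKind = v@inputKind)
}

## g. on chromosome of `assembly` -> g. on a covering gene-region record
chromosomeToRegion <- function(gv, refset, acc) {
  reg <- refset@regions[[acc]]
  asm <- gv@assembly
  if (is.null(reg) || !(asm %in% names(reg$span)) ||
      reg$chromosome[[asm]] != gv@accession)
    vsError("vs_no_path",
            sprintf("gene region %s does not cover %s on %s", acc,
                    gv@accession, asm))
  span <- reg$span[[asm]]
  if (gv@start@base <= span[1] || gv@end@base > span[2])
    vsError("vs_no_path",
            sprintf("variant lies outside gene region %s", acc))
  flip <- reg$orientation == "-"
  mapPos <- function(p) if (!flip) p@base - span[1] else span[2] - p@base + 1L
  r1 <- mapPos(gv@start); r2 <- mapPos(gv@end)
  rstart <- min(r1, r2); rend <- max(r1, r2)
  regSeq <- refset@sequences[[acc]]
  refSeq <- if (gv@edit@kind %in%
                c("deletion", "duplication", "inversion", "identity"))
    seqSlice(regSeq, rstart, rend, what = acc)
  else if (gv@edit@kind == "substitution")
    seqSlice(regSeq, rstart, rstart, what = acc)
  else NULL
  new("ParsedVariant", accession = acc, coordType = "g",
      start = hgvsPosition(rstart), end = hgvsPosition(rend),
      edit = reviseEdit(gv@edit, refSeq, flip),
      assembly = asm, inputKind = gv@inputKind)
}

## cross-build bridge: always via a shared transcript, endpoint-wise
crossBuildGenomic <- function(gv, refset, targetAssembly) {
  srcAsm <- gv@assembly
  hits <- findOverlappingTranscripts(refset, srcAsm, gv@accession,
                                     gv@start@base, gv@end@base)
  hits <- Filter(function(tx) targetAssembly %in% names(tx@exons), hits)
  if (!length(hits))
    vsError("vs_no_path",
            sprintf("no transcript bridges %s (%s) to assembly %s",
                    gv@accession, srcAsm, targetAssembly))
  tx <- hits[[1L]]
  mapPos <- function(g1) {
    np <- genomicToTx(g1, tx, srcAsm)
    txToGenomic(np, tx, targetAssembly, strict = FALSE)
  }
  p1 <- mapPos(gv@start@base); p2 <- mapPos(gv@end@base)
  gstart <- min(p1$pos, p2$pos); gend <- max(p1$pos, p2$pos)
  refSeq <- if (gv@edit@kind %in%
                c("deletion", "duplication", "inversion", "identity"))
    genomicRefSlice(refset, p1$chrom, gstart, gend)
  else if (gv@edit@kind == "substitution")
    genomicRefSlice(refset, p1$chrom, gstart, gstart)
  else NULL
  new("ParsedVariant", accession = p1$chrom, coordType = "g",
      start = hgvsPosition(gstart), end = hgvsPosition(gend),
      edit = reviseEdit(gv@edit, refSeq, FALSE),
      assembly = targetAssembly, inputKind = gv@inputKind)
}

## genomic variant -> transcript frame (c. when coding, else n.)
genomicToTranscriptVariant <- function(gv, tx, refset, assembly,
                                       coordType = NULL) {
  if (is.null(coordType)) coordType <- if (isCoding(tx)) "c" else "n"
  flip <- tx@strand == "-"
  n1 <- genomicToTx(gv@start@base, tx, assembly)
  n2 <- genomicToTx(gv@end@base, tx, assembly)
  if (flip) { tmp <- n1; n1 <- n2; n2 <- tmp }
  refSeq <- if (gv@edit@kind %in%
                c("deletion", "duplication", "inversion", "identity",
                  "substitution"))
    governingBases(n1, n2, tx, assembly, refset)
  else NULL
  new("ParsedVariant", accession = tx@accession, coordType = coordType,
      start = fromTxFrame(n1, coordType, tx),
      end = fromTxFrame(n2, coordType, tx),
      edit = reviseEdit(gv@edit, refSeq, flip),
      assembly = assembly, inputKind = gv@inputKind)
}

#' Project a variant between reference frames
#'
#' Projects a validated variant onto another reference context: a transcript
#' accession (c./n. frame), a chromosome or gene-region accession (g. frame),
#' or a build label (g. frame on that build's chromosome; the bridge between
#' builds is always a shared transcript).  Interval endpoints project
#' independently; the stated reference bases of the output are re-read from
#' the target sequence, so transcript-genome mismatches yield the correct
#' (different) bases on each side.  Conversion edits refuse projection.
#'
#' @param v a \linkS4class{ParsedVariant}
#' @param target accession or build label
#' @param refset a \linkS4class{ReferenceSet}
#' @param assembly source build label (defaults to the variant's hint, then
#'   the config default)
#' @return a \linkS4class{ParsedVariant} in the target frame
#' @export
projectVariant <- function(v, target, refset, assembly = NULL) {
  if (v@edit@kind == "conversion")
    vsError("vs_conversion_unsupported",
            "conversion mapping unsupported: conversion descriptions parse but cannot be projected")
  assembly <- assembly %||% v@assembly %||% refset@config$defaultAssembly
  if (is.na(assembly)) assembly <- refset@config$defaultAssembly

  if (target %in% names(refset@assemblies))
    return(variantToGenomic(v, refset, target))

  tacc <- resolveAccession(refset, target, warnUnversioned = FALSE)
  if (is.na(tacc))
    vsError("vs_no_path", sprintf("unknown projection target %s", target))
  mt <- refset@moltype[[tacc]]
  if (mt == "transcript") {
    tx <- refset@transcripts[[tacc]]
    txAsm <- if (assembly %in% names(tx@exons)) assembly
             else names(tx@exons)[1L]
    gv <- variantToGenomic(v, refset, txAsm)
    return(genomicToTranscriptVariant(gv, tx, refset, txAsm))
  }
  if (mt == "chromosome") {
    asm <- assemblyOfChromosome(refset, tacc)
    gv <- variantToGenomic(v, refset, asm)
    return(gv)
  }
  if (mt == "gene_region") {
    reg <- refset@regions[[tacc]]
    if (is.null(reg))
      vsError("vs_no_path",
              sprintf("no region mapping on file for %s", tacc))
    asm <- if (assembly %in% names(reg$span)) assembly
           else names(reg$span)[1L]
    gv <- variantToGenomic(v, refset, asm)
    return(chromosomeToRegion(gv, refset, tacc))
  }
  vsError("vs_no_path",
          sprintf("no projection path from %s to %s frame", v@coordType, mt))
}
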