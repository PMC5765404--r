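## Reference-data model: loaders, resolution and overlap queries over the
## bundle written by generateFixture() (or any bundle in the same layout).
## File layout (all spans 1-based inclusive in the files, interbase inside):
##   sequences.fa    multi-record FASTA, names = accessions
##   seqinfo.tsv     accession, moltype, description
##   transcripts.tsv accession, gene_symbol, gene_name, strand, assembly,
##                   chromosome, exon_index, g_start, g_end, tx_start, tx_end,
##                   cigar, cds_start, cds_end, description
##   regions.tsv     accession, gene_symbol, assembly, chromosome, chrom_start,
##                   chrom_end, orientation
##   crossrefs.tsv   alias, target, sequence_identical
##   assemblies.tsv  assembly, chrom_token, accession

#' Default configuration for a reference bundle
#'
#' The reference class of an accession is inferred from its prefix; only
#' curated classes (chromosome, gene-region, coding/non-coding transcript,
#' protein) take part in mapping.  The default map covers RefSeq prefixes and
#' the synthetic-fixture analogues; alias prefixes mark tokens resolved
#' through the cross-reference table.
#'
#' @param prefixMap named character vector: accession prefix (regex anchor)
#'   -> class in chromosome/gene_region/transcript/protein
#' @param aliasPrefixes prefixes routed through the cross-reference table
#' @param defaultAssembly build label used when none is supplied
#' @return a config list
#' @export
refConfig <- function(prefixMap = c(
                        "NC_"  = "chromosome",
                        "NG_"  = "gene_region",
                        "NM_"  = "transcript",
                        "NR_"  = "transcript",
                        "NP_"  = "protein",
                        "CTY"  = "chromosome",
                        "GG"   = "gene_region",
                        "TX"   = "transcript"),
                      aliasPrefixes = c("LRG_", "ENS"),
                      defaultAssembly = "TB1") {
  list(prefixMap = prefixMap, aliasPrefixes = aliasPrefixes,
       defaultAssembly = defaultAssembly)
}

## class of an accession under the config prefix map, or NA
accessionClass <- function(acc, config) {
  for (p in names(config$prefixMap))
    if (startsWith(acc, p)) return(unname(config$prefixMap[[p]]))
  NA_character_
}

isAliasToken <- function(acc, config) {
  any(vapply(config$aliasPrefixes, function(p) startsWith(acc, p), logical(1)))
}

#' Built-in GRCh chromosome-token table
#'
#' Maps pseudo-VCF chromosome tokens ("1".."22", "X", "Y") to RefSeq
#' chromosome accessions for GRCh37 and GRCh38, so pseudo-VCF descriptions
#' against the human builds resolve without a loaded bundle.
#'
#' @param assembly "GRCh37" or "GRCh38"
#' @return named character vector token -> accession, or NULL
#' @export
grchChromosomeMap <- function(assembly) {
  v37 <- c(10L, 11L, 11L, 11L, 9L, 11L, 13L, 10L, 11L, 10L, 9L, 11L, 10L,
           8L, 9L, 9L, 10L, 9L, 9L, 10L, 8L, 10L, 10L, 9L)
  tok <- c(as.character(1:22), "X", "Y")
  acc <- sprintf("NC_%06d", 1:24)
  if (identical(assembly, "GRCh37")) {
    stats::setNames(paste0(acc, ".", v37), tok)
  } else if (identical(assembly, "GRCh38")) {
    stats::setNames(paste0(acc, ".", v37 + 1L), tok)
  } else NULL
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "", colClasses = NA)
}

#' Load a reference data bundle
#'
#' Reads the FASTA and table files of a bundle directory into a fully
#' cross-validated \linkS4class{ReferenceSet}.  Referential-integrity or type
#' invariant violations are rejected at load time with an error naming the
#' offending accession and rule.
#'
#' @param dataDir bundle directory
#' @param config a \code{\link{refConfig}} list
#' @return a \linkS4class{ReferenceSet}
#' @export
loadReferenceSet <- function(dataDir, config = refConfig()) {
  need <- c("sequences.fa", "seqinfo.tsv", "transcripts.tsv", "regions.tsv",
            "crossrefs.tsv", "assemblies.tsv")
  for (f in need)
    if (!file.exists(file.path(dataDir, f)))
      stop("reference bundle is missing file: ", f, call. = FALSE)

  fa <- Biostrings::readBStringSet(file.path(dataDir, "sequences.fa"))
  seqs <- toupper(as.character(fa))
  names(seqs) <- sub("\\s.*$", "", names(fa))
  if (anyDuplicated(names(seqs)))
    stop("duplicate accession in sequences.fa: ",
         names(seqs)[duplicated(names(seqs))][1], call. = FALSE)

  info <- readTsv(file.path(dataDir, "seqinfo.tsv"))
  moltype <- stats::setNames(info$moltype, info$accession)
  descr <- stats::setNames(info$description, info$accession)
  for (acc in names(seqs)) {
    if (!nzchar(seqs[[acc]]))
      stop("empty sequence for accession ", acc, call. = FALSE)
    if (is.na(moltype[acc]))
      stop("sequence ", acc, " has no seqinfo row", call. = FALSE)
    if (moltype[[acc]] %in% c("chromosome", "gene_region", "transcript") &&
        !grepl("^[ACGTN]+$", seqs[[acc]]))
      stop("sequence ", acc, " contains non-ACGTN characters", call. = FALSE)
  }

  asmTab <- readTsv(file.path(dataDir, "assemblies.tsv"))
  assemblies <- lapply(split(asmTab, asmTab$assembly), function(d)
    stats::setNames(d$accession, d$chrom_token))
  for (a in names(assemblies))
    for (acc in assemblies[[a]])
      if (!(acc %in% names(seqs)))
        stop("assembly ", a, " references unknown sequence ", acc,
             call. = FALSE)

  txTab <- readTsv(file.path(dataDir, "transcripts.tsv"))
  transcripts <- list()
  if (nrow(txTab)) {
    for (acc in unique(txTab$accession)) {
      rows <- txTab[txTab$accession == acc, , drop = FALSE]
      exons <- list()
      for (asm in unique(rows$assembly)) {
        r <- rows[rows$assembly == asm, , drop = FALSE]
        r <- r[order(r$exon_index), , drop = FALSE]
        chrom <- unique(r$chromosome)
        if (length(chrom) != 1L)
          stop("transcript ", acc, " maps to several chromosomes in ", asm,
               call. = FALSE)
        if (!(chrom %in% names(seqs)))
          stop("transcript ", acc, " cites unknown sequence ", chrom,
               call. = FALSE)
        blocks <- data.frame(
          tx_start = r$tx_start - 1L, tx_end = r$tx_end,
          g_start = r$g_start - 1L, g_end = r$g_end,
          cigar = r$cigar, stringsAsFactors = FALSE)
        if (any(blocks$g_end > nchar(seqs[[chrom]])))
          stop("transcript ", acc, " exon exceeds ", chrom, " length",
               call. = FALSE)
        exons[[asm]] <- list(chrom = chrom, blocks = blocks)
      }
      cdsRow <- rows[1L, ]
      cds <- if (is.na(cdsRow$cds_start)) integer(0)
             else c(cdsRow$cds_start - 1L, cdsRow$cds_end)
      if (!(acc %in% names(seqs)))
        stop("transcript ", acc, " has no sequence record", call. = FALSE)
      transcripts[[acc]] <- new("TranscriptRecord",
        accession = acc, geneSymbol = cdsRow$gene_symbol,
        geneName = cdsRow$gene_name, strand = cdsRow$strand,
        exons = exons, cds = as.integer(cds),
        description = cdsRow$description)
      if (nchar(seqs[[acc]]) != transcriptLength(transcripts[[acc]]))
        stop("transcript ", acc, " sequence length disagrees with its ",
             "exon spans", call. = FALSE)
    }
  }

  regTab <- readTsv(file.path(dataDir, "regions.tsv"))
  regions <- list()
  if (nrow(regTab)) {
    for (acc in unique(regTab$accession)) {
      r <- regTab[regTab$accession == acc, , drop = FALSE]
      if (!(acc %in% names(seqs)))
        stop("gene region ", acc, " has no sequence record", call. = FALSE)
      span <- list(); chromv <- character(0)
      for (i in seq_len(nrow(r))) {
        chrom <- r$chromosome[i]
        if (!(chrom %in% names(seqs)))
          stop("gene region ", acc, " cites unknown sequence ", chrom,
               call. = FALSE)
        sp <- c(r$chrom_start[i] - 1L, r$chrom_end[i])
        if (sp[2] - sp[1] != nchar(seqs[[acc]]))
          stop("gene region ", acc, " span length disagrees with its ",
               "sequence in ", r$assembly[i], call. = FALSE)
        span[[r$assembly[i]]] <- as.integer(sp)
        chromv[r$assembly[i]] <- chrom
      }
      regions[[acc]] <- list(accession = acc, gene_symbol = r$gene_symbol[1],
                             chromosome = chromv, span = span,
                             orientation = r$orientation[1])
    }
  }

  xr <- readTsv(file.path(dataDir, "crossrefs.tsv"))
  if (nrow(xr)) {
    bad <- !(xr$target %in% c(names(seqs)))
    if (any(bad))
      stop("cross-reference ", xr$alias[bad][1], " targets unknown accession ",
           xr$target[bad][1], call. = FALSE)
  }

  new("ReferenceSet", sequences = seqs, moltype = moltype,
      seqDescriptions = descr, transcripts = transcripts, regions = regions,
      crossRefs = xr, assemblies = assemblies, config = config)
}

## Resolve an accession token to a canonical accession present in `sequences`.
## Order: exact match; cross-reference alias; unversioned -> highest loaded
## version (with a warning).  Returns NA when nothing matches.
resolveAccession <- function(refset, token, warnUnversioned = TRUE) {
  if (token %in% names(refset@sequences)) return(token)
  xr <- refset@crossRefs
  hit <- which(xr$alias == token)
  if (length(hit)) {
    row <- xr[hit[1L], ]
    if (startsWith(token, "ENS") && !isTRUE(as.logical(row$sequence_identical)))
      return(NA_character_)
    return(row$target)
  }
  if (!grepl("\\.", token)) {
    vers <- names(refset@sequences)[
      grepl(paste0("^", gsub("([.|()\\^{}+$*?])", "\\\\\\1", token),
                   "\\.[0-9]+$"),
            names(refset@sequences))]
    if (length(vers)) {
      v <- as.integer(sub("^.*\\.", "", vers))
      best <- vers[which.max(v)]
      if (warnUnversioned)
        warning("unversioned accession ", token, " resolved to ", best,
                call. = FALSE)
      return(best)
    }
  }
  NA_character_
}

#' Retrieve a (sub)sequence from a reference set
#'
#' @param refset a \linkS4class{ReferenceSet}
#' @param acc accession; cross-reference aliases and unversioned accessions
#'   resolve (the latter to the highest loaded version, with a warning)
#' @param start,end optional 1-based inclusive interval; both absent returns
#'   the full sequence
#' @return character scalar
#' @export
getSequence <- function(refset, acc, start = NULL, end = NULL) {
  res <- resolveAccession(refset, acc)
  if (is.na(res))
    stop("cannot resolve accession: ", acc, call. = FALSE)
  seq <- refset@sequences[[res]]
  if (is.null(start) && is.null(end)) return(seq)
  seqSlice(seq, as.integer(start), as.integer(end), what = res)
}

#' Resolve an input token to a reference record
#'
#' Versioned accessions resolve to their records; LRG-style aliases resolve
#' through the cross-reference table; Ensembl-style aliases resolve only when
#' a sequence-identical curated transcript is on file; a token matching a
#' known gene symbol returns a gene-symbol diagnosis carrying that gene's
#' transcript accessions (HGVS nomenclature does not allow a gene symbol in
#' place of a reference sequence).
#'
#' @param refset a \linkS4class{ReferenceSet}
#' @param token non-empty identifier string
#' @return a list with \code{$type} in \code{"transcript"},
#'   \code{"sequence"}, \code{"gene_symbol"}, \code{"unknown"}; plus
#'   \code{$record} (TranscriptRecord), \code{$accession}, or
#'   \code{$transcripts} (gene-symbol diagnosis)
#' @export
resolveReference <- function(refset, token) {
  stopifnot(nzchar(token))
  symbols <- vapply(refset@transcripts, geneSymbol, character(1))
  if (token %in% symbols) {
    return(list(type = "gene_symbol", symbol = token,
                transcripts = names(symbols)[symbols == token]))
  }
  acc <- suppressWarnings(resolveAccession(refset, token))
  if (is.na(acc)) return(list(type = "unknown", token = token))
  if (acc %in% names(refset@transcripts))
    return(list(type = "transcript", accession = acc,
                record = refset@transcripts[[acc]]))
  list(type = "sequence", accession = acc,
       moltype = unname(refset@moltype[acc]))
}

## genomic footprint (interbase) of a transcript on one assembly
txFootprint <- function(tx, assembly) {
  ex <- tx@exons[[assembly]]
  if (is.null(ex)) return(NULL)
  list(chrom = ex$chrom,
       span = c(min(ex$blocks$g_start), max(ex$blocks$g_end)))
}

#' Transcripts overlapping a genomic interval
#'
#' Returns every curated transcript whose genomic footprint (first exon start
#' to last exon end, introns included) intersects the query interval.
#'
#' @param refset a \linkS4class{ReferenceSet}
#' @param assembly build label
#' @param chrom chromosome accession (or token of that assembly)
#' @param start,end 1-based inclusive genomic interval
#' @return named list of \linkS4class{TranscriptRecord}
#' @export
findOverlappingTranscripts <- function(refset, assembly, chrom, start, end) {
  if (!(assembly %in% names(refset@assemblies)))
    stop("unknown assembly '", assembly, "'; available: ",
         paste(names(refset@assemblies), collapse = ", "), call. = FALSE)
  amap <- refset@assemblies[[assembly]]
  if (chrom %in% names(amap)) chrom <- amap[[chrom]]
  q <- c(start - 1L, end)  # interbase
  hits <- Filter(function(tx) {
    fp <- txFootprint(tx, assembly)
    !is.null(fp) && fp$chrom == chrom && fp$span[1] < q[2] && q[1] < fp$span[2]
  }, refset@transcripts)
  hits[vapply(hits, function(tx)
    identical(accessionClass(accession(tx), refset@config), "transcript"),
    logical(1))]
}

## chromosome accession for a token under an assembly; refset may be NULL
## (falls back to the built-in GRCh tables)
chromAccessionForToken <- function(token, assembly, refset = NULL) {
  token <- sub("^chr", "", token)
  if (!is.null(refset) && assembly %in% names(refset@assemblies)) {
    amap <- refset@assemblies[[assembly]]
    if (token %in% names(amap)) return(unname(amap[[token]]))
    if (token %in% amap) return(token)
  }
  gm <- grchChromosomeMap(assembly)
  if (!is.null(gm) && token %in% names(gm)) return(unname(gm[[token]]))
  NA_character_
}

## token under which a chromosome accession is published in an assembly map
chromTokenForAccession <- function(refset, assembly, acc) {
  amap <- refset@assemblies[[assembly]]
  if (!is.null(amap)) {
    i <- match(acc, amap)
    if (!is.na(i)) return(names(amap)[i])
  }
  acc
}
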