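## Small shared helpers.  Sequences are plain uppercase character scalars
## internally; Biostrings does the heavy lifting for I/O, complementation and
## the genetic code.

revcomp <- function(x) {
  if (!nzchar(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## substring by 1-based inclusive coordinates with bounds checking
seqSlice <- function(seq, start1, end1, what = "sequence") {
  n <- nchar(seq)
  if (start1 < 1L || end1 > n || start1 > end1)
    stop(sprintf("interval %d..%d is outside %s (length %d)",
                 start1, end1, what, n), call. = FALSE)
  substr(seq, start1, end1)
}

## replace seq[start1..end1] (1-based inclusive; start1 = end1 + 1 inserts
## before start1) by `with`
spliceSeq <- function(seq, start1, end1, with) {
  paste0(substr(seq, 1L, start1 - 1L), with,
         substr(seq, end1 + 1L, nchar(seq)))
}

## parse a CIGAR over {M,I,D} into op/length vectors
cigarOps <- function(cigar) {
  m <- gregexpr("([0-9]+)([MID])", cigar, perl = TRUE)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(cigar))
    stop("malformed CIGAR string: ", cigar, call. = FALSE)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MID]", cigar))[[1]]
  list(op = substr(toks, nchar(toks), nchar(toks)),
       len = as.integer(substr(toks, 1L, nchar(toks) - 1L)))
}

cigarLengths <- function(cigar) {
  co <- cigarOps(cigar)
  list(tx = sum(co$len[co$op %in% c("M", "I")]),
       g  = sum(co$len[co$op %in% c("M", "D")]))
}

transcriptLength <- function(tx) {
  b <- tx@exons[[1]]$blocks
  sum(b$tx_end - b$tx_start)
}

isCoding <- function(tx) length(tx@cds) == 2L

## Ordering of HgvsPosition under transcript/genomic 5'->3' reading:
## region rank (5'UTR < body < 3'UTR), then base, then offset.
positionCompare <- function(a, b) {
  rank <- function(p) if (p@utr3) 2L else if (p@base < 0L) 0L else 1L
  ra <- rank(a); rb <- rank(b)
  if (ra != rb) return(sign(ra - rb))
  if (a@base != b@base) return(sign(a@base - b@base))
  sign(a@offset - b@offset)
}

positionEqual <- function(a, b) positionCompare(a, b) == 0L

isNucleotideString <- function(x) grepl("^[ACGTN]+$", x)

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a
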