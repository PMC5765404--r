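## Deterministic synthetic reference bundle.  TOY1 emulates, at desk scale,
## the structures a curated human bundle provides: multi-exon genes on both
## strands, multiple transcripts over one locus, a transcript-genome base
## mismatch inside an aligned exon, a homopolymer run spanning an exon/intron
## junction, a gene-level (RefSeqGene-like) record, and two genome builds
## related by a fixed +24 coordinate shift.

SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

randBases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

## overwrite chrom[start1..end1] with `with` (lengths must agree)
plant <- function(seq, start1, with) {
  stopifnot(start1 + nchar(with) - 1L <= nchar(seq))
  spliceSeq(seq, start1, start1 + nchar(with) - 1L, with)
}

#' Generate a synthetic reference bundle
#'
#' Writes a complete reference data bundle (FASTA, transcript-model,
#' region-map, cross-reference and assembly tables, plus a small VCF) to
#' \code{dir} and returns it loaded.  Generation is deterministic: the same
#' name and seed always produce byte-identical files.
#'
#' The \code{TOY1} bundle contains assembly TB1 with chromosome CTY1.1
#' (2000 bp): GENE1 (+ strand) transcript TX1.1 with exons at g.1001-1100,
#' 1301-1400 and 1601-1700 and CDS at transcript positions 11-250; a T
#' homopolymer spanning the exon-1/intron-1 junction (g.1097-1103); a planted
#' transcript-genome mismatch (genome A at g.1350, transcript C at the
#' aligned base c.140); TX2.1 sharing exons 2-3 with its own first exon at
#' g.1201-1250; GENE2 (- strand) with coding TX3.1 (exons g.300-400 and
#' g.500-600) and non-coding TX4.1 (single exon g.480-560); gene-region
#' record GG1.1 spanning g.901-1800 (+ orientation); assembly TB2 identical
#' to TB1 with 24 bases prepended (chromosome CTY1.2; every TB2 coordinate =
#' TB1 + 24); and cross-references LRG_1 -> GG1.1, LRG_1t1 -> TX1.1 and
#' ENSTOY1 -> TX1.1 (sequence-identical).
#'
#' @param name fixture identifier; only "TOY1" is defined
#' @param seed integer RNG seed for the unconstrained bases
#' @param dir output directory (created if needed)
#' @return the loaded \linkS4class{ReferenceSet} (invisibly the files are on
#'   disk in \code{dir})
#' @export
generateFixture <- function(name = "TOY1", seed = 1L, dir = tempfile("toy1_")) {
  if (!identical(name, "TOY1"))
    stop("unknown fixture name: ", name, call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  chrom <- randBases(2000L)

  ## --- TX1.1 (GENE1, + strand): 300 nt, CDS tx 11..250 (80 codons) ----------
  codons <- c("ATG", sample(SENSE_CODONS, 78L, replace = TRUE), "TAA")
  ## codon 29 ends T, second base non-T: the junction T-run starts at c.87
  codons[29] <- paste0(sample(c("A", "C", "G", "T"), 1L),
                       sample(c("A", "C", "G"), 1L), "T")
  codons[30] <- "TTT"  # c.88-90 = g.1098-1100, exon-1 tail of the T run
  codons[47] <- "ACA"  # c.139-141; genome carries A at the middle base
  tx1 <- paste0(randBases(10L), paste(codons, collapse = ""), randBases(50L))

  ## exons g.1001-1100 / 1301-1400 / 1601-1700 (1-based inclusive)
  chrom <- plant(chrom, 1001L, substr(tx1, 1L, 100L))
  chrom <- plant(chrom, 1301L, substr(tx1, 101L, 200L))
  chrom <- plant(chrom, 1601L, substr(tx1, 201L, 300L))
  chrom <- plant(chrom, 1350L, "A")     # mismatch: genome A, transcript C
  chrom <- plant(chrom, 1101L, "TTTGT") # intron run tail; g.1104 breaks the
                                        # run, g.1105 = T for splice examples

  ## --- TX2.1 (GENE1): own exon 1 at g.1201-1250, shares exons 2-3 -----------
  ## CDS tx 3..200; frame matches TX1 over the shared exons, so the planted
  ## sense codons guarantee no internal stop (the mismatch codon reads AAA).
  tx2exon1 <- paste0(randBases(2L), "ATG",
                     paste(sample(SENSE_CODONS, 15L, replace = TRUE),
                           collapse = ""))
  chrom <- plant(chrom, 1201L, tx2exon1)
  tx2 <- paste0(tx2exon1, substr(chrom, 1301L, 1400L),
                substr(chrom, 1601L, 1700L))

  ## --- TX3.1 (GENE2, - strand): 202 nt, CDS tx 11..190 (60 codons) ----------
  tx3 <- paste0(randBases(10L),
                paste(c("ATG", sample(SENSE_CODONS, 58L, replace = TRUE),
                        "TAA"), collapse = ""),
                randBases(12L))
  chrom <- plant(chrom, 500L, revcomp(substr(tx3, 1L, 101L)))
  chrom <- plant(chrom, 300L, revcomp(substr(tx3, 102L, 202L)))

  ## --- TX4.1 (GENE2, - strand, non-coding): single exon g.480-560 -----------
  tx4 <- revcomp(substr(chrom, 480L, 560L))

  gg1 <- substr(chrom, 901L, 1800L)
  pad <- randBases(24L)
  chrom2 <- paste0(pad, chrom)

  seqs <- c(CTY1.1 = chrom, CTY1.2 = chrom2, GG1.1 = gg1,
            TX1.1 = tx1, TX2.1 = tx2, TX3.1 = tx3, TX4.1 = tx4)
  info <- data.frame(
    accession = names(seqs),
    moltype = c("chromosome", "chromosome", "gene_region",
                rep("transcript", 4L)),
    description = c(
      "Toylandia habilis chromosome TY1, build TB1",
      "Toylandia habilis chromosome TY1, build TB2",
      "Toylandia habilis gene one (GENE1), RefSeqGene-style record",
      "Toylandia habilis gene one (GENE1), transcript variant 1, mRNA",
      "Toylandia habilis gene one (GENE1), transcript variant 2, mRNA",
      "Toylandia habilis gene two (GENE2), transcript variant 1, mRNA",
      "Toylandia habilis gene two (GENE2), transcript variant 2, non-coding RNA"),
    stringsAsFactors = FALSE)

  exonRow <- function(acc, sym, nm, strand, asm, chromAcc, i, g1, g2, t1, t2,
                      cds1, cds2, desc) {
    data.frame(accession = acc, gene_symbol = sym, gene_name = nm,
               strand = strand, assembly = asm, chromosome = chromAcc,
               exon_index = i, g_start = g1, g_end = g2,
               tx_start = t1, tx_end = t2,
               cigar = paste0(t2 - t1 + 1L, "M"),
               cds_start = cds1, cds_end = cds2, description = desc,
               stringsAsFactors = FALSE)
  }
  txDefs <- list(
    list(acc = "TX1.1", sym = "GENE1", nm = "toy gene one", strand = "+",
         ex = cbind(g1 = c(1001L, 1301L, 1601L), g2 = c(1100L, 1400L, 1700L),
                    t1 = c(1L, 101L, 201L), t2 = c(100L, 200L, 300L)),
         cds = c(11L, 250L)),
    list(acc = "TX2.1", sym = "GENE1", nm = "toy gene one", strand = "+",
         ex = cbind(g1 = c(1201L, 1301L, 1601L), g2 = c(1250L, 1400L, 1700L),
                    t1 = c(1L, 51L, 151L), t2 = c(50L, 150L, 250L)),
         cds = c(3L, 200L)),
    list(acc = "TX3.1", sym = "GENE2", nm = "toy gene two", strand = "-",
         ex = cbind(g1 = c(500L, 300L), g2 = c(600L, 400L),
                    t1 = c(1L, 102L), t2 = c(101L, 202L)),
         cds = c(11L, 190L)),
    list(acc = "TX4.1", sym = "GENE2", nm = "toy gene two", strand = "-",
         ex = cbind(g1 = 480L, g2 = 560L, t1 = 1L, t2 = 81L),
         cds = c(NA_integer_, NA_integer_)))
  txTab <- do.call(rbind, lapply(txDefs, function(d) {
    desc <- info$description[info$accession == d$acc]
    do.call(rbind, lapply(c(TB1 = 0L, TB2 = 24L), function(shift) {
      asm <- if (shift == 0L) "TB1" else "TB2"
      chromAcc <- if (shift == 0L) "CTY1.1" else "CTY1.2"
      do.call(rbind, lapply(seq_len(nrow(d$ex)), function(i)
        exonRow(d$acc, d$sym, d$nm, d$strand, asm, chromAcc, i,
                d$ex[i, "g1"] + shift, d$ex[i, "g2"] + shift,
                d$ex[i, "t1"], d$ex[i, "t2"], d$cds[1], d$cds[2], desc)))
    }))
  }))

  regTab <- data.frame(
    accession = "GG1.1", gene_symbol = "GENE1",
    assembly = c("TB1", "TB2"), chromosome = c("CTY1.1", "CTY1.2"),
    chrom_start = c(901L, 925L), chrom_end = c(1800L, 1824L),
    orientation = "+", stringsAsFactors = FALSE)

  xrTab <- data.frame(
    alias = c("LRG_1", "LRG_1t1", "ENSTOY1"),
    target = c("GG1.1", "TX1.1", "TX1.1"),
    sequence_identical = TRUE, stringsAsFactors = FALSE)

  asmTab <- data.frame(
    assembly = c("TB1", "TB2"), chrom_token = "CTY1",
    accession = c("CTY1.1", "CTY1.2"), stringsAsFactors = FALSE)

  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, file.path(dir, "sequences.fa"), width = 70L)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(info, "seqinfo.tsv")
  wt(txTab, "transcripts.tsv")
  wt(regTab, "regions.tsv")
  wt(xrTab, "crossrefs.tsv")
  wt(asmTab, "assemblies.tsv")

  ## small companion VCF exercising SNV, multi-allelic, indel and symbolic ALT
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=CTY1,length=2000>",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           paste("CTY1", 1105L, ".", substr(chrom, 1105L, 1105L), "A",
                 ".", "PASS", ".", sep = "\t"),
           paste("CTY1", 1350L, ".", "A", "G,C",
                 ".", "PASS", ".", sep = "\t"),
           paste("CTY1", 1097L, ".", substr(chrom, 1097L, 1098L),
                 substr(chrom, 1097L, 1097L), ".", "PASS", ".", sep = "\t"),
           paste("CTY1", 400L, ".", substr(chrom, 400L, 400L), "<DEL>",
                 ".", "PASS", ".", sep = "\t"))
  writeLines(vcf, file.path(dir, "toy1.vcf"))

  rs <- loadReferenceSet(dir, refConfig())
  attr(rs, "dir") <- dir
  rs
}
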