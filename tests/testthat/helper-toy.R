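# Shared fixtures and independent oracles.  The TOY1 bundle is generated
# once per test run; oracles below re-derive string surgery and equivalence
# classes from first principles, independently of the package's edit engine.

.toyEnv <- new.env(parent = emptyenv())

toyRefSet <- function() {
  if (is.null(.toyEnv$rs)) {
    .toyEnv$dir <- file.path(tempdir(), "varscribe-toy1")
    .toyEnv$rs <- generateFixture("TOY1", seed = 1L, dir = .toyEnv$dir)
  }
  .toyEnv$rs
}

toyDir <- function() {
  toyRefSet()
  .toyEnv$dir
}

## minimal in-code reference set: one chromosome, no transcripts
miniRefSet <- function(context, chromAcc = "MC1.1", token = "M1",
                       assembly = "MB1") {
  seqs <- stats::setNames(toupper(context), chromAcc)
  cfg <- refConfig(prefixMap = c(MC = "chromosome", CTY = "chromosome",
                                 GG = "gene_region", TX = "transcript"),
                   defaultAssembly = assembly)
  new("ReferenceSet", sequences = seqs,
      moltype = stats::setNames("chromosome", chromAcc),
      seqDescriptions = stats::setNames("mini test chromosome", chromAcc),
      transcripts = list(), regions = list(),
      crossRefs = data.frame(alias = character(0), target = character(0),
                             sequence_identical = logical(0)),
      assemblies = stats::setNames(
        list(stats::setNames(chromAcc, token)), assembly),
      config = cfg)
}

## ---- independent string-surgery oracle ----------------------------------
oracleDelete <- function(ctx, i, j)
  paste0(substr(ctx, 1, i - 1), substr(ctx, j + 1, nchar(ctx)))
oracleInsert <- function(ctx, p, s)  # insert s after position p
  paste0(substr(ctx, 1, p), s, substr(ctx, p + 1, nchar(ctx)))
oracleReplace <- function(ctx, i, j, s)
  paste0(substr(ctx, 1, i - 1), s, substr(ctx, j + 1, nchar(ctx)))

## apply a VCF-style (pos, ref, alt) record by pure replacement
oracleApplyVcf <- function(ctx, pos, ref, alt) {
  stopifnot(substr(ctx, pos, pos + nchar(ref) - 1) == ref)
  oracleReplace(ctx, pos, pos + nchar(ref) - 1, alt)
}

## maximal-position equivalent placement of a deletion, by enumeration
oracleMaxDeletion <- function(ctx, i, j) {
  target <- oracleDelete(ctx, i, j)
  L <- j - i + 1
  best <- NULL
  for (s in seq_len(nchar(ctx) - L + 1)) {
    if (oracleDelete(ctx, s, s + L - 1) == target) best <- c(s, s + L - 1)
  }
  as.integer(best)
}

## maximal-position equivalent placement of an insertion (p = 5' flank)
oracleMaxInsertion <- function(ctx, p, s) {
  target <- oracleInsert(ctx, p, s)
  L <- nchar(s)
  best <- NULL
  for (q in 0:nchar(ctx)) {
    cand <- substr(target, q + 1, q + L)
    if (oracleInsert(ctx, q, cand) == target) best <- list(p = q, alt = cand)
  }
  best
}

## apply the positioned edit a normalized ParsedVariant describes, using
## only its printed coordinates (1-based on ctx) and the oracle surgery
oracleApplyGVariant <- function(ctx, v) {
  s <- v@start@base; e <- v@end@base
  switch(v@edit@kind,
    substitution = oracleReplace(ctx, s, e, v@edit@alt),
    deletion = oracleDelete(ctx, s, e),
    duplication = oracleInsert(ctx, e, substr(ctx, s, e)),
    insertion = oracleInsert(ctx, s, v@edit@alt),
    delins = oracleReplace(ctx, s, e, v@edit@alt),
    identity = ctx,
    stop("oracle cannot apply ", v@edit@kind))
}

## ---- structural comparison of parsed variants ---------------------------
posEq <- function(a, b)
  a@base == b@base && a@offset == b@offset && a@utr3 == b@utr3

variantEq <- function(a, b) {
  identical(a@accession, b@accession) &&
    identical(a@companion, b@companion) &&
    identical(a@legacyCompanion, b@legacyCompanion) &&
    identical(a@coordType, b@coordType) &&
    posEq(a@start, b@start) && posEq(a@end, b@end) &&
    identical(a@edit@kind, b@edit@kind) &&
    identical(a@edit@ref, b@edit@ref) &&
    identical(a@edit@alt, b@edit@alt) &&
    identical(a@edit@conSource, b@edit@conSource)
}

## ---- grammar fuzzer: random well-formed ParsedVariant -------------------
randomVariant <- function() {
  bases <- c("A", "C", "G", "T")
  nt <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
  coordType <- sample(c("g", "c", "n"), 1)
  rpos <- function(minBase = 1L) {
    if (coordType == "g")
      return(hgvsPosition(sample(1:99999, 1)))
    region <- sample(c("utr5", "body", "utr3"), 1,
                     prob = c(0.15, 0.7, 0.15))
    base <- switch(region, utr5 = -sample(1:200, 1),
                   body = sample(1:5000, 1), utr3 = sample(1:300, 1))
    offset <- if (coordType %in% c("c", "n") && stats::runif(1) < 0.3)
      sample(c(-1L, 1L), 1) * sample(1:500, 1) else 0L
    hgvsPosition(base, offset, utr3 = region == "utr3")
  }
  start <- rpos()
  span <- sample(0:5, 1)
  bumpBase <- function(b, k) {           # advance k bases, skipping base 0
    out <- b + k
    if (b < 0 && out >= 0) out <- out + 1L
    out
  }
  end <- if (span == 0) start else
    hgvsPosition(bumpBase(start@base, span), start@offset, start@utr3)
  kind <- sample(c("substitution", "deletion", "duplication", "insertion",
                   "delins", "inversion", "identity"), 1)
  edit <- switch(kind,
    substitution = { end <- start; edit_("substitution", nt(1), nt(1)) },
    deletion = edit_("deletion",
                     ref = if (stats::runif(1) < 0.6) nt(span + 1) else
                       NA_character_),
    duplication = edit_("duplication",
                        ref = if (stats::runif(1) < 0.6) nt(span + 1) else
                          NA_character_),
    insertion = {
      end <- hgvsPosition(bumpBase(start@base, 1L), start@offset, start@utr3)
      edit_("insertion", alt = nt(sample(1:6, 1)))
    },
    delins = edit_("delins", alt = nt(sample(1:6, 1))),
    inversion = {
      if (span == 0) end <- hgvsPosition(bumpBase(start@base, 1L),
                                         start@offset, start@utr3)
      edit_("inversion")
    },
    identity = edit_("identity"))
  acc <- sample(c("TX1.1", "NM_000088.3", "NC_000001.10", "GG1.1",
                  "NR_0001.2"), 1)
  companion <- NA_character_
  if (coordType %in% c("c", "n") && stats::runif(1) < 0.25)
    companion <- sample(c("GG1.1", "NG_008123.1", "NC_000001.10"), 1)
  if (coordType == "g") {
    start <- hgvsPosition(abs(start@base))
    end <- hgvsPosition(start@base + span)
    if (kind == "substitution") end <- start
    if (kind == "insertion") end <- hgvsPosition(start@base + 1L)
    if (kind == "inversion" && span == 0) end <- hgvsPosition(start@base + 1L)
  }
  new("ParsedVariant", accession = acc, companion = companion,
      coordType = coordType, start = start, end = end, edit = edit,
      inputKind = if (!is.na(companion)) "composed_hgvs" else "hgvs")
}

## report result-set signature for fixed-point comparisons (ignores the
## input echo and info diagnostics)
reportSignature <- function(r) {
  list(
    genomic = sort(unname(genomicDescriptions(r, normalized = TRUE))),
    pvcf = sort(unname(stats::na.omit(pseudoVcf(r)))),
    tx = sort(unname(transcriptDescriptions(r))),
    prot = sort(unname(proteinPredictions(r))))
}

reportProblems <- function(r)
  diagnosticCodes(r)[diagnosticSeverities(r) %in% c("warning", "error")]
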