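## Input dialects -> ParsedVariant, and back to canonical strings.
##
## Accepted dialects:
##   hgvs              TX1.1:c.90+5T>A, NC_000001.10:g.150550916G>A
##   composed_hgvs     GG1.1(TX1.1):c.90+5T>A  (outer genomic companion)
##   pseudo_vcf_dash   1-150550916-G-A         (needs an assembly)
##   pseudo_vcf_colon  1:150550916G>A          (needs an assembly)
##   hybrid_hgvs_vcf   NC_000016.9:g.2099572TC>T  (raw triple, minimized later)
##   gene_symbol_style COL5A1:c.5071A>T        (parses; guidance later)
##
## The edit grammar covers substitution, del, dup, ins, delins, inv,
## con (parse-only) and identity ("=").  Protein (p.) input is recognized and
## refused with guidance: predictions are output-only.

parseError <- function(msg, text, token = NULL, at = NA_integer_) {
  detail <- if (!is.null(token))
    sprintf(" (offending token \"%s\"%s)", token,
            if (!is.na(at)) sprintf(" at character %d", at) else "")
  else ""
  stop(structure(class = c("vs_parse_error", "error", "condition"),
                 list(message = paste0(msg, detail, " in \"", text, "\""),
                      call = NULL)))
}

POS_RE <- "(?:\\*?-?[0-9]+(?:[+-][0-9]+)?)"

parsePos <- function(s, text) {
  m <- regmatches(s, regexec("^(\\*?)(-?[0-9]+)([+-][0-9]+)?$", s))[[1]]
  if (!length(m)) parseError("invalid position", text, token = s)
  utr3 <- m[2] == "*"
  base <- as.integer(m[3])
  if (base == 0L) parseError("HGVS positions have no base 0", text, token = s)
  if (utr3 && base < 0L) parseError("invalid star position", text, token = s)
  offset <- if (nzchar(m[4])) as.integer(m[4]) else 0L
  hgvsPosition(base, offset, utr3)
}

## interval part "POS" or "POS_POS" -> list(start, end)
parseInterval <- function(s, text) {
  parts <- strsplit(s, "_", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    p <- parsePos(parts, text)
    list(start = p, end = p)
  } else if (length(parts) == 2L) {
    iv <- list(start = parsePos(parts[1], text), end = parsePos(parts[2], text))
    if (positionCompare(iv$start, iv$end) > 0L)
      parseError("interval start lies 3' of its end", text, token = s)
    iv
  } else parseError("invalid interval", text, token = s)
}

## posedit of a g/c/n description -> list(start, end, edit, hybrid)
parsePosEdit <- function(pe, coordType, text) {
  grab <- function(re) {
    m <- regmatches(pe, regexec(re, pe, perl = TRUE))[[1]]
    if (length(m)) m else NULL
  }
  ivre <- sprintf("(%s(?:_%s)?)", POS_RE, POS_RE)

  ## conversion (parse-only): POS_POS con <ref>:<type>.POS_POS
  m <- grab(sprintf("^(%s_%s)con([^ ]+)$", POS_RE, POS_RE))
  if (!is.null(m)) {
    src <- m[3]
    if (!grepl(sprintf("^[^:()\\s]+:[gcn]\\.%s_%s$", POS_RE, POS_RE), src))
      parseError("invalid conversion source span", text, token = src)
    iv <- parseInterval(m[2], text)
    return(c(iv, list(edit = edit_("conversion", conSource = src))))
  }
  m <- grab(sprintf("^%sdelins([ACGTNacgtn]+)$", ivre))
  if (!is.null(m)) {
    iv <- parseInterval(m[2], text)
    return(c(iv, list(edit = edit_("delins", alt = m[3]))))
  }
  m <- grab(sprintf("^%sdel([ACGTNacgtn]*)$", ivre))
  if (!is.null(m)) {
    iv <- parseInterval(m[2], text)
    ref <- if (nzchar(m[3])) m[3] else NA_character_
    return(c(iv, list(edit = edit_("deletion", ref = ref))))
  }
  m <- grab(sprintf("^%sdup([ACGTNacgtn]*)$", ivre))
  if (!is.null(m)) {
    iv <- parseInterval(m[2], text)
    ref <- if (nzchar(m[3])) m[3] else NA_character_
    return(c(iv, list(edit = edit_("duplication", ref = ref))))
  }
  m <- grab(sprintf("^(%s)_(%s)ins([ACGTNacgtn]+)$", POS_RE, POS_RE))
  if (!is.null(m)) {
    return(list(start = parsePos(m[2], text), end = parsePos(m[3], text),
                edit = edit_("insertion", alt = m[4])))
  }
  m <- grab(sprintf("^%sinv([ACGTNacgtn]*)$", ivre))
  if (!is.null(m)) {
    iv <- parseInterval(m[2], text)
    if (positionEqual(iv$start, iv$end))
      parseError("an inversion needs a multi-base interval", text, token = pe)
    ref <- if (nzchar(m[3])) m[3] else NA_character_
    return(c(iv, list(edit = edit_("inversion", ref = ref))))
  }
  m <- grab(sprintf("^%s=$", ivre))
  if (!is.null(m)) {
    iv <- parseInterval(m[2], text)
    return(c(iv, list(edit = edit_("identity"))))
  }
  ## substitution; multi-base ref/alt on a single g. position = hybrid triple
  m <- grab(sprintf("^(%s)([ACGTNacgtn]+)>([ACGTNacgtn]+)$", POS_RE))
  if (!is.null(m)) {
    ref <- toupper(m[3]); alt <- toupper(m[4])
    if (nchar(ref) == 1L && nchar(alt) == 1L) {
      p <- parsePos(m[2], text)
      return(list(start = p, end = p, edit = edit_("substitution", ref, alt)))
    }
    if (coordType == "g") {
      p <- parsePos(m[2], text)
      return(list(start = p,
                  end = hgvsPosition(p@base + nchar(ref) - 1L),
                  edit = edit_("delins", ref = ref, alt = alt),
                  hybrid = TRUE))
    }
    parseError("multi-base ref>alt is only accepted on g. positions",
               text, token = pe)
  }
  parseError("unrecognized position/edit", text, token = pe)
}

LEGACY_TX_RE <- "^[A-Za-z0-9-]+_v[0-9]+$"

#' Parse a variant description
#'
#' Auto-detects the dialect and returns a \linkS4class{ParsedVariant}.
#' Pseudo-VCF dialects require an assembly to resolve the chromosome token to
#' an accession (built-in GRCh37/GRCh38 tables are consulted when no
#' \code{refset} is supplied).  Hybrid HGVS:VCF descriptions (multi-base
#' ref/alt after a single g. position) parse as a raw triple for later
#' minimization.  Gene-symbol-prefixed input parses but is tagged
#' \code{gene_symbol_style}.  Protein (p.) descriptions are refused with
#' guidance: they are prediction output, not validatable input.
#'
#' @param text the description; surrounding whitespace is trimmed and base
#'   case normalized to upper
#' @param assembly optional build label (required for pseudo-VCF dialects)
#' @param refset optional \linkS4class{ReferenceSet} used to resolve
#'   pseudo-VCF chromosome tokens
#' @return a \linkS4class{ParsedVariant}
#' @export
parseVariant <- function(text, assembly = NULL, refset = NULL) {
  raw <- text
  text <- trimws(text)
  if (!nzchar(text)) parseError("empty variant description", raw)

  ## pseudo-VCF, dash dialect: CHROM-POS-REF-ALT
  m <- regmatches(text, regexec(
    "^(chr)?([A-Za-z0-9._]+)-([0-9]+)-([ACGTNacgtn]+)-([ACGTNacgtn]+)$",
    text))[[1]]
  if (length(m))
    return(pseudoVcfVariant(m[3], m[4], m[5], m[6], "pseudo_vcf_dash",
                            assembly, refset, text))
  ## pseudo-VCF, colon dialect: CHROM:POSREF>ALT
  m <- regmatches(text, regexec(
    "^(chr)?([A-Za-z0-9._]+):([0-9]+)([ACGTNacgtn]+)>([ACGTNacgtn]+)$",
    text))[[1]]
  if (length(m) && !grepl(":[gcnp]\\.", text))
    return(pseudoVcfVariant(m[3], m[4], m[5], m[6], "pseudo_vcf_colon",
                            assembly, refset, text))

  ## HGVS proper (possibly composed)
  m <- regmatches(text, regexec(
    "^([^:()[:space:]]+)(\\(([^()]+)\\))?:([gcnpGCNP])\\.(.+)$", text))[[1]]
  if (!length(m))
    parseError("unrecognized variant description syntax", text,
               token = substr(text, 1L, 30L), at = 1L)
  outer <- m[2]; inner <- m[4]; coordType <- tolower(m[5]); pe <- m[6]
  if (coordType == "p")
    stop(structure(class = c("vs_protein_input", "vs_parse_error", "error",
                             "condition"),
                   list(message = paste0(
                     "protein (p.) descriptions are prediction output and ",
                     "cannot be validated as input; submit the underlying ",
                     "nucleotide description instead: \"", text, "\""),
                     call = NULL)))

  companion <- NA_character_
  legacy <- NA_character_
  primary <- outer
  inputKind <- "hgvs"
  if (nzchar(inner)) {
    inputKind <- "composed_hgvs"
    if (grepl(LEGACY_TX_RE, inner) && !grepl("\\.", inner)) {
      legacy <- inner            # e.g. NG_(GENE1_v003):c. -- legacy designation
      companion <- NA_character_
    } else {
      companion <- outer         # NG_(NM_):c. -- inner transcript is primary
      primary <- inner
    }
  }
  looksSymbol <- !grepl("\\.", primary) &&
    !grepl("^(LRG_|ENS)", primary) && !grepl("_v[0-9]+$", primary) &&
    grepl("^[A-Za-z][A-Za-z0-9-]*$", primary)
  if (looksSymbol && coordType %in% c("c", "n") && is.na(companion))
    inputKind <- "gene_symbol_style"

  ped <- parsePosEdit(pe, coordType, text)
  if (isTRUE(ped$hybrid)) inputKind <- "hybrid_hgvs_vcf"
  if (coordType == "g" &&
      (ped$start@offset != 0L || ped$end@offset != 0L ||
       ped$start@utr3 || ped$end@utr3 || ped$start@base < 1L))
    parseError("g. positions take no offsets or UTR anchors", text, token = pe)
  new("ParsedVariant", accession = primary, companion = companion,
      legacyCompanion = legacy, coordType = coordType,
      start = ped$start, end = ped$end, edit = ped$edit,
      assembly = assembly %||% NA_character_, inputKind = inputKind)
}

pseudoVcfVariant <- function(tok, pos, ref, alt, kind, assembly, refset, text) {
  if (is.null(assembly) || !nzchar(assembly))
    parseError("assembly required for pseudo-VCF descriptions", text,
               token = tok)
  acc <- chromAccessionForToken(tok, assembly, refset)
  if (is.na(acc)) acc <- tok  # resolved later against a loaded bundle
  ref <- toupper(ref); alt <- toupper(alt)
  pos <- as.integer(pos)
  if (ref == alt) {
    ed <- edit_("identity", ref = ref)
  } else if (nchar(ref) == 1L && nchar(alt) == 1L) {
    ed <- edit_("substitution", ref, alt)
  } else {
    ed <- edit_("delins", ref = ref, alt = alt)  # raw triple; minimized later
  }
  new("ParsedVariant", accession = acc, coordType = "g",
      start = hgvsPosition(pos),
      end = hgvsPosition(pos + nchar(ref) - 1L),
      edit = ed, assembly = assembly, inputKind = kind)
}

formatPosition <- function(p) {
  paste0(if (p@utr3) "*" else "", p@base,
         if (p@offset != 0L) sprintf("%+d", p@offset) else "")
}

formatInterval <- function(start, end) {
  if (positionEqual(start, end)) formatPosition(start)
  else paste0(formatPosition(start), "_", formatPosition(end))
}

formatEdit <- function(e, verbose = TRUE) {
  switch(e@kind,
    substitution = paste0(e@ref, ">", e@alt),
    deletion = paste0("del", if (verbose && !is.na(e@ref)) e@ref else ""),
    duplication = paste0("dup", if (verbose && !is.na(e@ref)) e@ref else ""),
    insertion = paste0("ins", e@alt),
    delins = paste0("delins", e@alt),
    inversion = paste0("inv", if (verbose && !is.na(e@ref)) e@ref else ""),
    conversion = paste0("con", e@conSource),
    identity = "=")
}

#' Format a parsed variant back to a description string
#'
#' @param v a \linkS4class{ParsedVariant}
#' @param style \code{"verbose_bases"} (default; echoes deleted/duplicated
#'   bases, e.g. delGTT), \code{"plain"} (minimal form), or
#'   \code{"composed"} (companion accession in parentheses)
#' @return character scalar; \code{parseVariant(formatVariant(v))} is
#'   structurally equal to \code{v}
#' @export
formatVariant <- function(v, style = c("verbose_bases", "plain", "composed")) {
  style <- match.arg(style)
  if (style == "composed" && is.na(v@companion))
    stop("composed style requires a companion accession", call. = FALSE)
  prefix <- if (style == "composed")
    paste0(v@companion, "(", v@accession, ")")
  else if (!is.na(v@companion))
    paste0(v@companion, "(", v@accession, ")")
  else if (!is.na(v@legacyCompanion))
    paste0(v@accession, "(", v@legacyCompanion, ")")
  else v@accession
  paste0(prefix, ":", v@coordType, ".",
         formatInterval(v@start, v@end),
         formatEdit(v@edit, verbose = style != "plain"))
}

#' Classify the dialect of a description string
#'
#' @param text a variant description
#' @return the \code{inputKind} the parser assigns, or "unknown" if the text
#'   does not parse
#' @export
classifyInput <- function(text) {
  v <- tryCatch(parseVariant(text, assembly = "GRCh38"),
                error = function(e) NULL)
  if (is.null(v)) "unknown" else v@inputKind
}
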