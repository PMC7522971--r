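#' @title HGVS coding-DNA (c.) notation
#' @description A parser and formatter for the HGVS c. dialect this pipeline
#' needs: substitutions, deletions, duplications, insertions and
#' deletion-insertions on CDS coordinates. The hyphenated range dialect seen
#' in some publications ("c.574-589del") is accepted on input when both sides
#' are plain positive integers, but the standard "_" separator is always
#' emitted. Intron-offset notation (c.88+2T>G) is not supported.
#' @name hgvs
NULL

#' Construct a coding-space variant
#'
#' An edit in 1-based CDS coordinates. Conventions per kind:
#' * `substitution`: `cds_start == cds_end`, `ref_seq`/`inserted_seq` one base each.
#' * `deletion`: bases `cds_start..cds_end` removed; `deleted_len = cds_end - cds_start + 1`.
#' * `duplication`: reference segment `cds_start..cds_end` inserted again after
#'   `cds_end`; `inserted_seq` is empty (filled from the CDS) or equals the segment.
#' * `insertion`: `inserted_seq` inserted after position `cds_start`
#'   (`cds_start == cds_end`, the left flank).
#' * `delins`: segment `cds_start..cds_end` replaced by `inserted_seq`.
#'
#' @param kind one of "substitution", "deletion", "duplication", "insertion",
#'   "delins"
#' @param cds_start,cds_end 1-based CDS positions (inclusive)
#' @param ref_seq reference bases (substitution/optionally deletion)
#' @param inserted_seq inserted bases (insertion/delins/optionally duplication)
#' @return object of class `CodingVariant`
#' @export
coding_variant <- function(kind, cds_start, cds_end = cds_start,
                           ref_seq = "", inserted_seq = "") {
  kind <- match.arg(kind, c("substitution", "deletion", "duplication",
                            "insertion", "delins"))
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  ref_seq <- toupper(ref_seq); inserted_seq <- toupper(inserted_seq)
  if (cds_start < 1 || cds_end < cds_start)
    stop("need 1 <= cds_start <= cds_end")
  chk_dna <- function(s, what) {
    if (nchar(s) && !is_dna(s)) stop(what, " must be over A,C,G,T")
  }
  chk_dna(ref_seq, "ref_seq"); chk_dna(inserted_seq, "inserted_seq")
  span <- cds_end - cds_start + 1L
  deleted_len <- 0L
  if (kind == "substitution") {
    if (span != 1L) stop("substitution must be a single position")
    if (nchar(ref_seq) != 1L || nchar(inserted_seq) != 1L)
      stop("substitution needs single-base ref_seq and inserted_seq")
    if (ref_seq == inserted_seq) stop("substitution ref equals alt")
  } else if (kind == "deletion") {
    deleted_len <- span
    if (nchar(ref_seq) && nchar(ref_seq) != span)
      stop("deleted sequence length does not match range")
  } else if (kind == "duplication") {
    if (nchar(inserted_seq) && nchar(inserted_seq) != span)
      stop("duplicated sequence length does not match range")
  } else if (kind == "insertion") {
    if (cds_start != cds_end)
      stop("insertion uses cds_start == cds_end (the left flank)")
    if (!nchar(inserted_seq)) stop("insertion requires a sequence")
  } else { # delins
    deleted_len <- span
    if (!nchar(inserted_seq)) stop("delins requires an inserted sequence")
  }
  obj <- list(kind = kind, cds_start = cds_start, cds_end = cds_end,
              ref_seq = ref_seq, inserted_seq = inserted_seq,
              deleted_len = deleted_len)
  class(obj) <- "CodingVariant"
  obj
}

#' @export
print.CodingVariant <- function(x, ...) {
  cat("CodingVariant:", format_hgvs_c(x), "\n")
  invisible(x)
}

#' Net length change of a coding edit
#'
#' Inserted length minus deleted length; a frameshift iff not divisible by 3.
#' For duplications with an unfilled sequence the span length is used.
#'
#' @param v a [coding_variant()]
#' @return integer net length change
#' @export
coding_net_change <- function(v) {
  ins_len <- if (v$kind == "duplication" && !nchar(v$inserted_seq)) {
    v$cds_end - v$cds_start + 1L
  } else nchar(v$inserted_seq)
  if (v$kind == "substitution") 0L else as.integer(ins_len) - v$deleted_len
}

#' Parse HGVS c. notation
#'
#' Supported: `[GENE:]c.<pos><REF>><ALT>`, `c.<s>[_<e>]del[SEQ]`,
#' `c.<s>[_<e>]dup[SEQ]`, `c.<s>_<e>ins<SEQ>`, `c.<s>[_<e>]delins<SEQ>`.
#' The "-" range separator is accepted between two plain positive integers
#' (publication dialect); intron offsets are rejected.
#'
#' @param text HGVS string, optionally prefixed "GENE:"
#' @return a [coding_variant()]
#' @export
parse_hgvs_c <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  body <- sub("^[A-Za-z0-9._()-]+:", "", text)
  if (!startsWith(body, "c.")) stop("not c. notation: ", text)
  body <- substr(body, 3L, nchar(body))
  if (grepl("^\\d+[+*]\\d|[_-]\\d+[+-]\\d", body))
    stop("unsupported dialect (intron/UTR offset notation): ", text)
  m <- regmatches(body, regexec("^(\\d+)([ACGTacgt])>([ACGTacgt])$", body))[[1]]
  if (length(m)) {
    return(coding_variant("substitution", as.integer(m[2]),
                          ref_seq = m[3], inserted_seq = m[4]))
  }
  m <- regmatches(body, regexec(
    "^(\\d+)(?:([_-])(\\d+))?(delins|del|dup|ins)([ACGTacgt]*)$", body))[[1]]
  if (!length(m)) stop("cannot parse HGVS c. expression: ", text)
  s <- as.integer(m[2]); sep <- m[3]
  e <- if (nchar(m[4])) as.integer(m[4]) else s
  op <- m[5]; seq <- toupper(m[6])
  if (e < s) {
    if (sep == "-")
      stop("unsupported dialect (intron-offset or inverted range): ", text)
    stop("inverted range in ", text)
  }
  span <- e - s + 1L
  if (op == "del") {
    if (nchar(seq) && nchar(seq) != span)
      stop("deleted sequence length (", nchar(seq),
           ") does not match range ", s, "_", e)
    coding_variant("deletion", s, e, ref_seq = seq)
  } else if (op == "dup") {
    if (nchar(seq) && nchar(seq) != span)
      stop("duplicated sequence length (", nchar(seq),
           ") does not match range ", s, "_", e)
    coding_variant("duplication", s, e, inserted_seq = seq)
  } else if (op == "ins") {
    if (!nchar(seq)) stop("insertion without sequence: ", text)
    if (e != s + 1L)
      stop("insertion flanks must be adjacent positions: ", text)
    coding_variant("insertion", s, inserted_seq = seq)
  } else {
    if (!nchar(seq)) stop("delins without sequence: ", text)
    coding_variant("delins", s, e, inserted_seq = seq)
  }
}

#' Format a coding variant in standard HGVS c. notation
#'
#' Always emits the standard "_" range separator; deletion/duplication
#' sequences are omitted (coordinates suffice against a reference).
#'
#' @param v a [coding_variant()]
#' @return character HGVS string (no gene prefix)
#' @export
format_hgvs_c <- function(v) {
  stopifnot(inherits(v, "CodingVariant"))
  rng <- if (v$cds_end > v$cds_start)
    paste0(v$cds_start, "_", v$cds_end) else as.character(v$cds_start)
  switch(v$kind,
    substitution = paste0("c.", v$cds_start, v$ref_seq, ">", v$inserted_seq),
    deletion = paste0("c.", rng, "del"),
    duplication = paste0("c.", rng, "dup"),
    insertion = paste0("c.", v$cds_start, "_", v$cds_start + 1L, "ins",
                       v$inserted_seq),
    delins = paste0("c.", rng, "delins", v$inserted_seq))
}

#' Protein-level summary for a consequence record
#'
#' Frameshifts are reported in the customary `p.<codon>fs*<offset>` style,
#' where the offset is the mutant stop's distance from the first affected
#' codon (or "?" when no stop was found).
#'
#' @param rec a ConsequenceRecord from [predict_consequence()]
#' @return character summary
#' @export
format_protein_summary <- function(rec) {
  stopifnot(inherits(rec, "ConsequenceRecord"))
  switch(rec$type,
    frameshift = paste0("p.", rec$first_affected_codon, "fs*",
                        rec$mut_stop_codon_index - rec$first_affected_codon + 1L),
    no_stop_found = paste0("p.", rec$first_affected_codon, "fs*?"),
    stop_gain = paste0("p.", rec$first_affected_codon, "*"),
    stop_loss = paste0("p.", rec$wt_stop_codon_index, "ext*",
                       rec$mut_stop_codon_index - rec$wt_stop_codon_index),
    start_loss = "p.1?",
    synonymous = paste0("p.", rec$first_affected_codon, "="),
    paste0("p.", rec$first_affected_codon))
}
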