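#' @title Coding-consequence engine
#' @description Applies CDS-space edits to a coding sequence, translates the
#' mutant reading frame from the original start codon, scans for the first
#' stop codon (continuing into the 3'UTR when a frameshift reads through the
#' reference stop), and classifies the consequence into VEP-style impact
#' tiers. Genomic variants are projected into CDS space through the
#' transcript's exon structure, strand-aware, with HGVS 3'-shifting of indels.
#' @name consequence
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

# standard genetic code, TCAG order
CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return(character())
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a nucleotide string (standard code)
#'
#' Translates complete codons from position 1; trailing partial codons are
#' ignored; unknown codons (containing N) become "X".
#'
#' @param s nucleotide string
#' @param to_stop stop at (and exclude) the first stop codon
#' @return character amino-acid string
#' @export
translate_cds <- function(s, to_stop = FALSE) {
  cods <- codon_split(toupper(s))
  aa <- CODON_TABLE[cods]
  aa[is.na(aa)] <- "X"
  if (to_stop) {
    k <- which(aa == "*")
    if (length(k)) aa <- aa[seq_len(k[1] - 1L)]
  }
  paste(aa, collapse = "")
}

first_stop_index <- function(s) {
  cods <- codon_split(toupper(s))
  k <- which(cods %in% STOP_CODONS)
  if (length(k)) k[1] else NA_integer_
}

#' First protein position affected by a coding edit
#'
#' Substitutions, deletions and delins affect the codon containing their first
#' edited base; insertions and duplications (inserted after `cds_end`) affect
#' the codon of the first inserted position, `cds_end + 1`.
#'
#' @param v a [coding_variant()]
#' @return 1-based codon index
#' @export
first_affected_codon <- function(v) {
  stopifnot(inherits(v, "CodingVariant"))
  pos <- if (v$kind %in% c("insertion", "duplication")) v$cds_end + 1L
         else v$cds_start
  (pos - 1L) %/% 3L + 1L
}

#' Apply a coding edit to a CDS string
#'
#' @param v a [coding_variant()]
#' @param cds reference CDS string
#' @return mutant CDS string
#' @export
apply_coding_edit <- function(v, cds) {
  stopifnot(inherits(v, "CodingVariant"))
  L <- nchar(cds)
  if (v$cds_end > L) stop("edit extends past CDS end (", v$cds_end, " > ", L, ")")
  seg <- substr(cds, v$cds_start, v$cds_end)
  if (v$kind == "substitution") {
    if (nchar(v$ref_seq) && v$ref_seq != seg)
      stop("reference mismatch at c.", v$cds_start, ": CDS has ", seg,
           ", variant states ", v$ref_seq)
    paste0(substr(cds, 1L, v$cds_start - 1L), v$inserted_seq,
           substr(cds, v$cds_start + 1L, L))
  } else if (v$kind == "deletion") {
    if (nchar(v$ref_seq) && v$ref_seq != seg)
      stop("deleted sequence mismatch at c.", v$cds_start, "_", v$cds_end)
    paste0(substr(cds, 1L, v$cds_start - 1L), substr(cds, v$cds_end + 1L, L))
  } else if (v$kind == "duplication") {
    ins <- if (nchar(v$inserted_seq)) v$inserted_seq else seg
    if (ins != seg)
      stop("duplicated sequence mismatch at c.", v$cds_start, "_", v$cds_end)
    paste0(substr(cds, 1L, v$cds_end), ins, substr(cds, v$cds_end + 1L, L))
  } else if (v$kind == "insertion") {
    paste0(substr(cds, 1L, v$cds_start), v$inserted_seq,
           substr(cds, v$cds_start + 1L, L))
  } else { # delins
    paste0(substr(cds, 1L, v$cds_start - 1L), v$inserted_seq,
           substr(cds, v$cds_end + 1L, L))
  }
}

new_consequence_record <- function(type, first_affected_codon = NA_integer_,
                                   wt_stop_codon_index = NA_integer_,
                                   mut_stop_codon_index = NA_integer_,
                                   is_frameshift = FALSE) {
  obj <- list(
    type = type,
    first_affected_codon = as.integer(first_affected_codon),
    wt_stop_codon_index = as.integer(wt_stop_codon_index),
    mut_stop_codon_index = as.integer(mut_stop_codon_index),
    wt_protein_len = as.integer(wt_stop_codon_index) - 1L,
    mut_protein_len = if (is.na(mut_stop_codon_index)) NA_integer_
                      else as.integer(mut_stop_codon_index) - 1L,
    is_frameshift = is_frameshift,
    impact = classify_impact(type))
  class(obj) <- "ConsequenceRecord"
  obj
}

#' @export
print.ConsequenceRecord <- function(x, ...) {
  cat("ConsequenceRecord:", x$type, "[", x$impact, "]\n",
      " first affected codon:", x$first_affected_codon,
      " wt stop:", x$wt_stop_codon_index,
      " mut stop:", x$mut_stop_codon_index, "\n")
  invisible(x)
}

#' Predict the protein-level consequence of a coding edit
#'
#' The edit is applied to the CDS, the mutant is translated from the original
#' start codon with the standard genetic code, and the reading is scanned
#' codon-by-codon for the first stop, continuing into the supplied 3'UTR if
#' none occurs within the edited CDS (a frameshift that reads through the
#' reference stop terminates, if at all, in former 3'UTR territory). Stop
#' indices are 1-based codon positions counted from the start codon;
#' `wt_protein_len`/`mut_protein_len` are residue counts excluding the stop.
#'
#' @param v a [coding_variant()]
#' @param cds reference CDS string, length divisible by 3, ending in a stop
#' @param utr3 3'UTR sequence appended for the stop scan (may be "")
#' @return object of class `ConsequenceRecord`
#' @export
predict_consequence <- function(v, cds, utr3 = "") {
  stopifnot(inherits(v, "CodingVariant"))
  cds <- toupper(cds); utr3 <- toupper(utr3)
  L <- nchar(cds)
  if (L %% 3L != 0L) stop("CDS length not divisible by 3")
  if (!substr(cds, L - 2L, L) %in% STOP_CODONS)
    stop("CDS does not end in a stop codon")
  if (v$cds_end > L) stop("variant outside CDS (cds_end ", v$cds_end, ")")
  wt_stop <- L %/% 3L
  m <- apply_coding_edit(v, cds)
  fac <- first_affected_codon(v)
  net <- nchar(m) - L
  shift <- net %% 3L != 0L
  if (substr(m, 1L, 3L) != "ATG")
    return(new_consequence_record("start_loss", 1L, wt_stop,
                                  is_frameshift = shift))
  mut_stop <- first_stop_index(paste0(m, utr3))
  if (is.na(mut_stop))
    return(new_consequence_record("no_stop_found", fac, wt_stop,
                                  is_frameshift = shift))
  type <- if (shift) {
    "frameshift"
  } else if (net == 0L) {
    if (mut_stop < wt_stop) "stop_gain"
    else if (mut_stop > wt_stop) "stop_loss"
    else if (translate_cds(m, to_stop = TRUE) ==
             translate_cds(cds, to_stop = TRUE)) "synonymous"
    else "missense"
  } else {
    expected <- wt_stop + net %/% 3L
    if (mut_stop < expected) "stop_gain"
    else if (mut_stop > expected) "stop_loss"
    else "inframe_indel"
  }
  new_consequence_record(type, fac, wt_stop, mut_stop, is_frameshift = shift)
}

#' Impact tier of a consequence
#'
#' Fixed ontology mirroring the VEP impact tiers for the consequence types
#' this engine emits.
#'
#' @param x a ConsequenceRecord or a consequence type string
#' @return one of "HIGH", "MODERATE", "LOW", "MODIFIER"
#' @export
classify_impact <- function(x) {
  type <- if (inherits(x, "ConsequenceRecord")) x$type else as.character(x)
  switch(type,
    frameshift = , stop_gain = , stop_loss = , start_loss = ,
    splice_region = , no_stop_found = "HIGH",
    missense = , inframe_indel = "MODERATE",
    synonymous = "LOW",
    "MODIFIER")
}

#' Percent protein enlargement of a stop-altering consequence
#'
#' `100 * (mut_protein_len - wt_protein_len) / wt_protein_len`; negative for
#' truncations.
#'
#' @param rec a ConsequenceRecord
#' @return numeric percentage
#' @export
percent_enlargement <- function(rec) {
  stopifnot(inherits(rec, "ConsequenceRecord"))
  100 * (rec$mut_protein_len - rec$wt_protein_len) / rec$wt_protein_len
}

# flat CDS coordinate lookup: 0-based genomic position -> 0-based index along
# the plus-orientation concatenated CDS, or NA
cds_flat_index <- function(t, gpos0) {
  offs <- cumsum(c(0L, t$cds$end - t$cds$start))
  for (i in seq_len(nrow(t$cds))) {
    if (gpos0 >= t$cds$start[i] && gpos0 < t$cds$end[i])
      return(offs[i] + (gpos0 - t$cds$start[i]))
  }
  NA_integer_
}

#' 3'UTR sequence of a transcript
#'
#' Exonic sequence downstream of the CDS in transcription order (after the
#' stop codon), spliced and strand-corrected.
#'
#' @param t a [transcript_model()]
#' @param ref a [reference_sequences()] set
#' @return character (possibly "")
#' @export
transcript_utr3 <- function(t, ref) {
  seq <- ref_seq(ref, t$chrom)
  if (t$strand == "+") {
    cds_end <- max(t$cds$end)
    parts <- character()
    for (i in seq_len(nrow(t$exons))) {
      s <- max(t$exons$start[i], cds_end); e <- t$exons$end[i]
      if (e > s) parts <- c(parts, substr(seq, s + 1L, e))
    }
    paste(parts, collapse = "")
  } else {
    cds_start <- min(t$cds$start)
    parts <- character()
    for (i in seq_len(nrow(t$exons))) {
      s <- t$exons$start[i]; e <- min(t$exons$end[i], cds_start)
      if (e > s) parts <- c(parts, substr(seq, s + 1L, e))
    }
    dna_revcomp(paste(rev(parts), collapse = ""))
  }
}

shift3_deletion <- function(cds, s, e) {
  L <- nchar(cds)
  while (e < L && substr(cds, s, s) == substr(cds, e + 1L, e + 1L)) {
    s <- s + 1L; e <- e + 1L
  }
  c(s, e)
}

shift3_insertion <- function(cds, p, q) {
  L <- nchar(cds)
  while (p < L && substr(q, 1L, 1L) == substr(cds, p + 1L, p + 1L)) {
    q <- paste0(substr(q, 2L, nchar(q)), substr(q, 1L, 1L))
    p <- p + 1L
  }
  list(p = p, q = q)
}

#' Project a genomic variant into CDS space
#'
#' Strips the VCF anchor base (shared prefix/suffix), maps the minimal edit
#' through the transcript's CDS intervals (reverse-complementing alleles and
#' reflecting coordinates for minus-strand models), and 3'-shifts indels to
#' their most-3' equivalent CDS position (HGVS normalisation); an insertion
#' whose sequence equals the immediately preceding CDS segment becomes a
#' duplication. Variants not touching the CDS yield a MODIFIER signal;
#' variants straddling a CDS/intron boundary yield a HIGH-impact
#' splice-region signal with no protein arithmetic.
#'
#' @param v one-row variant (data.frame row or list with chrom, pos, ref, alt)
#' @param t a [transcript_model()]
#' @param ref a [reference_sequences()] set
#' @return list with `status` ("coding", "splice_region", "non_coding"),
#'   `coding_variant` (a [coding_variant()], coding only), `impact`, and the
#'   original genomic representation (`chrom`, `pos`, `ref`, `alt`)
#' @export
project_to_cds <- function(v, t, ref) {
  chrom <- as.character(v$chrom); pos <- as.integer(v$pos)
  r <- toupper(as.character(v$ref)); a <- toupper(as.character(v$alt))
  if (chrom != t$chrom)
    return(projection(v, "non_coding"))
  seq <- ref_seq(ref, t$chrom)
  if (substr(seq, pos, pos + nchar(r) - 1L) != r)
    stop("REF allele mismatch against reference at ", chrom, ":", pos)
  # minimal edit: trim shared prefix, then shared suffix
  np <- 0L
  while (np < min(nchar(r), nchar(a)) &&
         substr(r, np + 1L, np + 1L) == substr(a, np + 1L, np + 1L)) np <- np + 1L
  r2 <- substr(r, np + 1L, nchar(r)); a2 <- substr(a, np + 1L, nchar(a))
  ns <- 0L
  while (ns < min(nchar(r2), nchar(a2)) &&
         substr(r2, nchar(r2) - ns, nchar(r2) - ns) ==
         substr(a2, nchar(a2) - ns, nchar(a2) - ns)) ns <- ns + 1L
  r2 <- substr(r2, 1L, nchar(r2) - ns); a2 <- substr(a2, 1L, nchar(a2) - ns)
  g0 <- pos - 1L + np  # 0-based start of deleted span / insertion gap
  ndel <- nchar(r2)
  L <- cds_length(t)
  cds <- spliced_cds(t, ref)
  if (ndel > 0L) {
    idx <- vapply(seq_len(ndel) - 1L, function(k) cds_flat_index(t, g0 + k),
                  integer(1))
    if (all(is.na(idx))) return(projection(v, "non_coding"))
    if (anyNA(idx)) return(projection(v, "splice_region"))
    if (t$strand == "+") { s <- idx[1] + 1L; e <- idx[ndel] + 1L }
    else { s <- L - idx[ndel]; e <- L - idx[1] }
    del_seq <- substr(cds, s, e)
    ins_seq <- if (t$strand == "-") dna_revcomp(a2) else a2
    cv <- if (nchar(ins_seq) == 0L) {
      se <- shift3_deletion(cds, s, e)
      coding_variant("deletion", se[1], se[2],
                     ref_seq = substr(cds, se[1], se[2]))
    } else if (ndel == 1L && nchar(ins_seq) == 1L) {
      coding_variant("substitution", s, ref_seq = del_seq,
                     inserted_seq = ins_seq)
    } else {
      coding_variant("delins", s, e, inserted_seq = ins_seq)
    }
    projection(v, "coding", cv)
  } else {
    # pure insertion between 0-based positions g0-1 and g0
    inside <- function(g) !is.na(cds_flat_index(t, g))
    if (!inside(g0 - 1L) || !inside(g0)) {
      # at or outside a CDS edge: splice-region if one flank is coding
      if (inside(g0 - 1L) || inside(g0))
        return(projection(v, "splice_region"))
      return(projection(v, "non_coding"))
    }
    il <- cds_flat_index(t, g0 - 1L); ir <- cds_flat_index(t, g0)
    if (abs(ir - il) != 1L) return(projection(v, "splice_region"))
    if (t$strand == "+") { p <- il + 1L; q <- a2 }
    else { p <- L - ir; q <- dna_revcomp(a2) }
    sh <- shift3_insertion(cds, p, q)
    p <- sh$p; q <- sh$q
    m <- nchar(q)
    cv <- if (p >= m && substr(cds, p - m + 1L, p) == q) {
      coding_variant("duplication", p - m + 1L, p, inserted_seq = q)
    } else {
      coding_variant("insertion", p, inserted_seq = q)
    }
    projection(v, "coding", cv)
  }
}

projection <- function(v, status, cv = NULL) {
  impact <- switch(status, coding = NA_character_,
                   splice_region = "HIGH", non_coding = "MODIFIER")
  list(status = status, coding_variant = cv, impact = impact,
       chrom = as.character(v$chrom), pos = as.integer(v$pos),
       ref = as.character(v$ref), alt = as.character(v$alt))
}

#' Annotate genomic variants against transcript models
#'
#' Projects each variant onto each overlapping transcript and predicts its
#' coding consequence. One row per (variant, transcript) pair whose gene span
#' contains the variant.
#'
#' @param variants data.frame from [variant_table()]
#' @param transcripts list of [transcript_model()]
#' @param ref a [reference_sequences()] set
#' @return data.frame: gene, transcript, chrom, pos, ref, alt, status,
#'   hgvs_c, protein, type, impact, wt_len, mut_len
#' @export
annotate_variants <- function(variants, transcripts, ref) {
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    for (t in transcripts) {
      span <- gene_span(t)
      if (v$chrom != t$chrom || v$pos - 1L < span[1] || v$pos - 1L >= span[2])
        next
      pr <- project_to_cds(v, t, ref)
      if (pr$status == "coding") {
        rec <- predict_consequence(pr$coding_variant, spliced_cds(t, ref),
                                   transcript_utr3(t, ref))
        rows[[length(rows) + 1L]] <- data.frame(
          gene = t$gene_id, transcript = t$transcript_id,
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          status = "coding", hgvs_c = format_hgvs_c(pr$coding_variant),
          protein = format_protein_summary(rec), type = rec$type,
          impact = rec$impact, wt_len = rec$wt_protein_len,
          mut_len = rec$mut_protein_len, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = t$gene_id, transcript = t$transcript_id,
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
          status = pr$status, hgvs_c = NA_character_, protein = NA_character_,
          type = pr$status, impact = pr$impact,
          wt_len = NA_integer_, mut_len = NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(), transcript = character(),
                      chrom = character(), pos = integer(), ref = character(),
                      alt = character(), status = character(),
                      hgvs_c = character(), protein = character(),
                      type = character(), impact = character(),
                      wt_len = integer(), mut_len = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
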