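#' @title Domain containers
#' @description Constructors and validators for the pipeline's core types:
#' variant tables, per-sample genotype calls, cohorts, transcript models and
#' reference sequences. Genomic intervals are held 0-based half-open
#' internally; VCF and GFF3 conversion happens at the I/O boundary. CDS and
#' protein coordinates are 1-based (HGVS convention).
#' @name datamodel
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

dna_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  grepl(pat, x)
}

#' Build a variant table
#'
#' A variant is a biallelic, sequence-resolved edit: `pos` is the 1-based
#' genomic position of the first REF base (VCF convention); `ref` and `alt`
#' are non-empty A/C/G/T strings and differ.
#'
#' @param chrom character, sequence names
#' @param pos integer, 1-based positions of the first REF base
#' @param ref,alt character, REF/ALT allele strings
#' @param id optional labels (defaults to `chrom:pos:ref:alt`)
#' @return data.frame with columns chrom, pos, ref, alt, id
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(), id = NULL) {
  chrom <- as.character(chrom); ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt)); pos <- as.integer(pos)
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  if (n > 0) {
    if (!all(is_dna(ref)) || !all(is_dna(alt)))
      stop("ref/alt alleles must be non-empty strings over A,C,G,T")
    if (any(ref == alt)) stop("ref and alt must differ")
    if (any(pos < 1)) stop("pos is 1-based and must be >= 1")
  }
  if (is.null(id)) id <- paste(chrom, pos, ref, alt, sep = ":")
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             id = as.character(id), stringsAsFactors = FALSE)
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Build a sample sheet
#'
#' @param sample_id unique sample identifiers
#' @param phenotype free-text phenotype labels (e.g. "Moyle", "Violet")
#' @param role one of "case", "control", "unassigned" per sample
#' @return data.frame with columns sample_id, phenotype, role
#' @export
sample_sheet <- function(sample_id, phenotype = "", role = "unassigned") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in sample sheet")
  role <- rep_len(as.character(role), length(sample_id))
  bad <- setdiff(unique(role), c("case", "control", "unassigned"))
  if (length(bad)) stop("invalid role(s): ", paste(bad, collapse = ", "))
  data.frame(sample_id = sample_id,
             phenotype = rep_len(as.character(phenotype), length(sample_id)),
             role = role, stringsAsFactors = FALSE)
}

#' Assemble a cohort of genotype calls
#'
#' The substrate of the segregation filter: an ordered variant table, an
#' ordered sample sheet, and per-(variant, sample) call matrices. Allele
#' matrices hold allele indices (0 = REF, 1 = ALT, NA = missing); `depth`
#' holds DP (NA = absent); `phased` records the GT separator ("|" vs "/").
#' Variants are sorted by (chrom, pos, ref, alt) on construction and call
#' matrices reordered along with them.
#'
#' @param variants data.frame from [variant_table()]
#' @param samples data.frame from [sample_sheet()]
#' @param allele_a,allele_b integer matrices (variants x samples) of allele
#'   indices in 0/1/NA
#' @param depth integer matrix of read depths (NA = absent)
#' @param phased logical matrix (defaults to all FALSE)
#' @return object of class `CohortGenotypes`
#' @export
cohort_genotypes <- function(variants, samples, allele_a, allele_b,
                             depth = NULL, phased = NULL) {
  nv <- nrow(variants); ns <- nrow(samples)
  as_mat <- function(m, what, default) {
    if (is.null(m)) m <- matrix(default, nv, ns)
    m <- as.matrix(m)
    if (!all(dim(m) == c(nv, ns)))
      stop(what, " matrix must be ", nv, " x ", ns)
    m
  }
  allele_a <- as_mat(allele_a, "allele_a", NA_integer_)
  allele_b <- as_mat(allele_b, "allele_b", NA_integer_)
  depth <- as_mat(depth, "depth", NA_integer_)
  phased <- as_mat(phased, "phased", FALSE)
  ok <- function(m) all(m %in% c(0L, 1L, NA_integer_))
  if (!ok(allele_a) || !ok(allele_b))
    stop("allele indices must be 0, 1 or NA (records are biallelic)")
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
  o <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
  variants <- variants[o, , drop = FALSE]
  rownames(variants) <- NULL
  reord <- function(m) m[o, , drop = FALSE]
  obj <- list(variants = variants, samples = samples,
              allele_a = reord(allele_a), allele_b = reord(allele_b),
              depth = reord(depth), phased = reord(phased))
  class(obj) <- "CohortGenotypes"
  obj
}

#' @export
print.CohortGenotypes <- function(x, ...) {
  cat("CohortGenotypes:", nrow(x$variants), "variants x",
      nrow(x$samples), "samples\n")
  tab <- table(factor(x$samples$role, c("case", "control", "unassigned")))
  cat("  roles:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.CohortGenotypes <- function(x) c(nrow(x$variants), nrow(x$samples))

#' Reference sequence set
#'
#' @param x named character vector of nucleotide strings (A/C/G/T/N)
#' @return named uppercase character vector of class `ReferenceSequences`
#' @export
reference_sequences <- function(x) {
  x <- toupper(unlist(x))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("reference sequences must be named")
  if (length(x) && !all(is_dna(x, allow_n = TRUE)))
    stop("reference sequences must be over A,C,G,T,N")
  class(x) <- "ReferenceSequences"
  x
}

ref_seq <- function(ref, chrom) {
  if (!chrom %in% names(ref)) stop("sequence not in reference: ", chrom)
  unclass(ref)[[chrom]]
}

interval_df <- function(start, end) {
  d <- data.frame(start = as.integer(start), end = as.integer(end))
  d <- d[order(d$start), , drop = FALSE]
  rownames(d) <- NULL
  if (any(d$end <= d$start)) stop("empty or inverted interval")
  if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
    stop("intervals overlap")
  d
}

#' Strand-aware transcript model
#'
#' Exon and CDS intervals are 0-based half-open genomic intervals, sorted by
#' genomic coordinate regardless of strand; `strand` controls the
#' genomic-to-coding projection. `cds` must be covered by the exon space and
#' includes the stop codon.
#'
#' @param gene_id,transcript_id identifiers
#' @param chrom sequence name
#' @param strand "+" or "-"
#' @param exons,cds data.frames with integer columns start, end (0-based
#'   half-open); cds a subset of the exon space
#' @return object of class `TranscriptModel`
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons, cds) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- interval_df(exons$start, exons$end)
  cds <- interval_df(cds$start, cds$end)
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    if (!inside) stop("CDS interval outside exon space in ", transcript_id)
  }
  obj <- list(gene_id = as.character(gene_id),
              transcript_id = as.character(transcript_id),
              chrom = as.character(chrom), strand = strand,
              exons = exons, cds = cds)
  class(obj) <- "TranscriptModel"
  obj
}

#' @export
print.TranscriptModel <- function(x, ...) {
  cat("TranscriptModel", x$transcript_id, "(", x$gene_id, ")",
      x$chrom, x$strand, "\n  exons:", nrow(x$exons),
      " CDS length:", cds_length(x), "nt\n")
  invisible(x)
}

cds_length <- function(t) sum(t$cds$end - t$cds$start)

gene_span <- function(t) c(min(t$exons$start), max(t$exons$end))

#' Spliced CDS sequence of a transcript
#'
#' Concatenates the CDS intervals in transcription order (reverse-complemented
#' for minus-strand models), yielding the coding sequence from ATG through the
#' stop codon.
#'
#' @param t a [transcript_model()]
#' @param ref a [reference_sequences()] set
#' @return character CDS string
#' @export
spliced_cds <- function(t, ref) {
  seq <- ref_seq(ref, t$chrom)
  parts <- vapply(seq_len(nrow(t$cds)), function(i) {
    substr(seq, t$cds$start[i] + 1L, t$cds$end[i])
  }, "")
  s <- paste(parts, collapse = "")
  if (t$strand == "-") s <- dna_revcomp(s)
  s
}

#' Validate a transcript's CDS against the reference
#'
#' Checks that the spliced CDS length is divisible by 3, begins with ATG and
#' ends with a stop codon. With `warn_only = TRUE` failures downgrade to
#' warnings (for annotation sets with known incomplete models).
#'
#' @param t a [transcript_model()]
#' @param ref a [reference_sequences()] set
#' @param warn_only logical; warn instead of erroring
#' @return invisibly, the spliced CDS string
#' @export
validate_transcript <- function(t, ref, warn_only = FALSE) {
  complain <- if (warn_only) warning else stop
  s <- spliced_cds(t, ref)
  if (nchar(s) %% 3 != 0)
    complain("CDS length of ", t$transcript_id, " (", nchar(s),
             ") not divisible by 3", call. = FALSE)
  else {
    if (substr(s, 1, 3) != "ATG")
      complain("CDS of ", t$transcript_id, " does not start with ATG",
               call. = FALSE)
    if (!substr(s, nchar(s) - 2, nchar(s)) %in% STOP_CODONS)
      complain("CDS of ", t$transcript_id, " does not end with a stop codon",
               call. = FALSE)
  }
  invisible(s)
}
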