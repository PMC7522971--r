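#' @title VCF and sample-sheet I/O
#' @description Reading goes through vcfR; this layer decomposes
#' multi-allelic records into biallelic variants, remaps per-sample allele
#' indices, and extracts GT/DP into the cohort call matrices. Writing emits
#' VCF v4.2 text directly so that header-only files and missing-value
#' conventions ("./.", DP ".") round-trip exactly.
#' @name vcf_io
NULL

empty_variant_table <- function() variant_table()

parse_gt_string <- function(gt, line, sample) {
  if (is.na(gt) || gt == ".") {
    return(list(a = NA_integer_, b = NA_integer_, phased = FALSE))
  }
  m <- regmatches(gt, regexec("^(\\.|[0-9]+)([/|])(\\.|[0-9]+)$", gt))[[1]]
  if (!length(m))
    stop("malformed GT '", gt, "' for sample ", sample, " at VCF line ", line)
  toi <- function(x) if (x == ".") NA_integer_ else as.integer(x)
  list(a = toi(m[2]), b = toi(m[4]), phased = m[3] == "|")
}

#' Read a multi-sample VCF into a cohort
#'
#' Consumes VCF v4.x (plain or gzip/bgzip) with GT and optionally DP FORMAT
#' fields. Multi-allelic records are decomposed into one biallelic variant
#' per ALT allele, with per-sample allele indices remapped (the k-th ALT
#' becomes allele 1 of the k-th record; other alleles become 0). Symbolic
#' ALTs and alleles outside A/C/G/T are skipped with a warning. Sample order
#' follows the VCF header; roles/phenotypes are attached from an optional
#' sample sheet.
#'
#' @param path VCF file
#' @param samples optional data.frame from [sample_sheet()] /
#'   [read_sample_sheet()]; must cover every VCF sample
#' @return a [cohort_genotypes()] object
#' @export
read_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  sample_ids <- if (!is.null(gt) && ncol(gt) > 1L) colnames(gt)[-1L] else character()
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id in VCF header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (is.null(samples)) {
    samples <- sample_sheet(sample_ids)
  } else {
    miss <- setdiff(sample_ids, samples$sample_id)
    if (length(miss))
      stop("samples missing from sample sheet: ", paste(miss, collapse = ", "))
    samples <- samples[match(sample_ids, samples$sample_id), , drop = FALSE]
    rownames(samples) <- NULL
  }
  ns <- length(sample_ids)
  header_lines <- length(vcf@meta) + 1L
  vt <- list(); aa <- list(); ab <- list(); dp <- list(); ph <- list()
  for (i in seq_len(nrow(fix))) {
    line <- header_lines + i
    ref <- toupper(fix[i, "REF"])
    alts <- strsplit(toupper(fix[i, "ALT"]), ",", fixed = TRUE)[[1]]
    keep <- !grepl("[<>\\[\\]*]", alts) & is_dna(alts) & is_dna(ref) &
      alts != ref
    if (any(!keep))
      warning("skipping symbolic/non-ACGT allele(s) at VCF line ", line,
              ": ", paste(alts[!keep], collapse = ","), call. = FALSE)
    fmt <- strsplit(gt[i, 1L], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop("no GT field at VCF line ", line)
    dp_idx <- match("DP", fmt)
    calls <- lapply(seq_len(ns), function(j) {
      parts <- strsplit(gt[i, j + 1L], ":", fixed = TRUE)[[1]]
      g <- parse_gt_string(parts[gt_idx], line, sample_ids[j])
      g$dp <- NA_integer_
      if (!is.na(dp_idx) && length(parts) >= dp_idx &&
          parts[dp_idx] != "." && !is.na(parts[dp_idx]))
        g$dp <- as.integer(parts[dp_idx])
      g
    })
    amax <- length(alts)
    for (j in seq_len(ns)) {
      g <- calls[[j]]
      if ((!is.na(g$a) && g$a > amax) || (!is.na(g$b) && g$b > amax))
        stop("allele index exceeds ALT count at VCF line ", line,
             " for sample ", sample_ids[j])
    }
    for (k in which(keep)) {
      vt[[length(vt) + 1L]] <- variant_table(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = alts[k],
        id = if (is.na(fix[i, "ID"]) || fix[i, "ID"] == ".") NULL
             else fix[i, "ID"])
      remap <- function(x) {
        if (is.na(x)) NA_integer_ else if (x == k) 1L else 0L
      }
      aa[[length(aa) + 1L]] <- vapply(calls, function(g) remap(g$a), integer(1))
      ab[[length(ab) + 1L]] <- vapply(calls, function(g) remap(g$b), integer(1))
      dp[[length(dp) + 1L]] <- vapply(calls, function(g) g$dp, integer(1))
      ph[[length(ph) + 1L]] <- vapply(calls, function(g) g$phased, logical(1))
    }
  }
  nv <- length(vt)
  bind <- function(lst, default) {
    if (nv == 0L) matrix(default, 0L, ns) else do.call(rbind, lst)
  }
  variants <- if (nv == 0L) empty_variant_table() else do.call(rbind, vt)
  cohort_genotypes(variants, samples,
                   allele_a = bind(aa, NA_integer_),
                   allele_b = bind(ab, NA_integer_),
                   depth = bind(dp, NA_integer_),
                   phased = bind(ph, FALSE))
}

#' Write a cohort as VCF v4.2
#'
#' Emits GT and DP FORMAT fields; missing alleles become "." within the GT,
#' missing depth becomes ".". `read_vcf(write_vcf(c))` reproduces the cohort
#' exactly (given the same sample sheet).
#'
#' @param cohort a [cohort_genotypes()] object
#' @param path output file
#' @return invisibly, `path`
#' @export
write_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "CohortGenotypes"))
  v <- cohort$variants
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=minkmap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample_id), collapse = "\t"))
  al <- function(x) ifelse(is.na(x), ".", as.character(x))
  for (i in seq_len(nrow(v))) {
    sep <- ifelse(cohort$phased[i, ], "|", "/")
    gts <- paste0(al(cohort$allele_a[i, ]), sep, al(cohort$allele_b[i, ]),
                  ":", al(cohort$depth[i, ]))
    lines <- c(lines, paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i],
                              v$alt[i], ".", ".", ".", "GT:DP", gts),
                            collapse = "\t"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a sample sheet (TSV: sample_id, phenotype, role)
#'
#' @param path TSV file with header `sample_id<TAB>phenotype<TAB>role`
#' @return data.frame from [sample_sheet()]
#' @export
read_sample_sheet <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "phenotype", "role")
  if (!all(need %in% names(d)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  sample_sheet(d$sample_id, d$phenotype, d$role)
}

#' Write a sample sheet
#'
#' @param samples data.frame from [sample_sheet()]
#' @param path output TSV
#' @return invisibly, `path`
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
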