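#' @title Recessive case/control segregation filter
#' @description The discovery filter: a gene is a candidate when every case
#' carries two mutant alleles of that gene — homozygous for an alternate
#' allele, or compound heterozygous (two or more heterozygous sites, phase
#' unresolved at this stage) — through depth-passing genotype calls, and no
#' control carries two mutant alleles over the implicated variants. Controls
#' exclude a gene only through affirmative evidence: a missing or low-depth
#' control genotype never removes a candidate, and a heterozygous carrier is
#' neither homozygous nor compound heterozygous, so it never excludes.
#' @name segregation
NULL

#' Filter parameters
#'
#' @param min_depth_exclusive genotypes count only when DP is present and
#'   strictly greater than this (default 2, i.e. DP >= 3)
#' @param require_called_in_all_cases if TRUE (default) a case with no
#'   usable genotype in a gene makes the gene fail; if FALSE, such cases are
#'   skipped and the rule applies to cases with called, depth-passing
#'   genotypes (at least one informative case is still required)
#' @return list of class `FilterParams`
#' @export
filter_params <- function(min_depth_exclusive = 2L,
                          require_called_in_all_cases = TRUE) {
  min_depth_exclusive <- as.integer(min_depth_exclusive)
  stopifnot(min_depth_exclusive >= 0L)
  structure(list(min_depth_exclusive = min_depth_exclusive,
                 require_called_in_all_cases = require_called_in_all_cases),
            class = "FilterParams")
}

#' Classify a genotype call
#'
#' (0,0) is hom_ref; (0,1) and (1,0) are het; (1,1) is hom_alt; any missing
#' allele makes the call missing. Vectorised over paired allele vectors.
#'
#' @param allele_a,allele_b allele indices (0, 1 or NA)
#' @return character vector over hom_ref/het/hom_alt/missing
#' @export
genotype_class <- function(allele_a, allele_b) {
  a <- as.integer(allele_a); b <- as.integer(allele_b)
  if (any(a > 1L | a < 0L, na.rm = TRUE) || any(b > 1L | b < 0L, na.rm = TRUE))
    stop("allele index out of range: records must be biallelic (0/1)")
  out <- rep("missing", length(a))
  called <- !is.na(a) & !is.na(b)
  s <- a[called] + b[called]
  out[called] <- c("hom_ref", "het", "hom_alt")[s + 1L]
  out
}

genotype_class_matrix <- function(cohort) {
  m <- matrix(genotype_class(cohort$allele_a, cohort$allele_b),
              nrow = nrow(cohort$variants))
  dimnames(m) <- list(cohort$variants$id, cohort$samples$sample_id)
  m
}

#' Depth filter for a genotype call
#'
#' TRUE iff depth is present and strictly greater than
#' `min_depth_exclusive` (at the default 2 this is DP >= 3). Vectorised.
#'
#' @param depth DP values (NA = absent)
#' @param params a [filter_params()] object
#' @return logical vector
#' @export
passes_depth <- function(depth, params = filter_params()) {
  !is.na(depth) & depth > params$min_depth_exclusive
}

# gene_id -> variant row indices; membership = position within
# [min exon start, max exon end) of any of the gene's transcripts, so
# intronic variants stay in (the filter runs genome-wide before annotation)
gene_variant_index <- function(cohort, transcripts) {
  v <- cohort$variants
  genes <- list()
  for (t in transcripts) {
    span <- gene_span(t)
    cur <- genes[[t$gene_id]]
    if (is.null(cur)) cur <- list(chrom = t$chrom, lo = span[1], hi = span[2])
    else { cur$lo <- min(cur$lo, span[1]); cur$hi <- max(cur$hi, span[2]) }
    genes[[t$gene_id]] <- cur
  }
  out <- list()
  if (!length(genes)) return(out)
  for (g in names(genes)) {
    sp <- genes[[g]]
    idx <- which(v$chrom == sp$chrom & (v$pos - 1L) >= sp$lo &
                 (v$pos - 1L) < sp$hi)
    out[[g]] <- idx
  }
  out[order(names(out))]
}

#' Candidate compound-heterozygous variant groups for one sample
#'
#' For each gene, the variants at which the sample is heterozygous with a
#' depth-passing call; genes with fewer than two such variants are dropped.
#' Phase is not consulted — cis configurations are resolved downstream by
#' [infer_phase()].
#'
#' @param cohort a [cohort_genotypes()] object
#' @param sample_id sample to inspect
#' @param transcripts list of [transcript_model()]
#' @param params a [filter_params()] object
#' @return named list: gene_id -> data.frame of variant rows
#' @export
compound_het_groups <- function(cohort, sample_id, transcripts,
                                params = filter_params()) {
  j <- match(sample_id, cohort$samples$sample_id)
  if (is.na(j)) stop("unknown sample_id: ", sample_id)
  cls <- genotype_class(cohort$allele_a[, j], cohort$allele_b[, j])
  dp <- passes_depth(cohort$depth[, j], params)
  gidx <- gene_variant_index(cohort, transcripts)
  out <- list()
  for (g in names(gidx)) {
    idx <- gidx[[g]]
    hets <- idx[cls[idx] == "het" & dp[idx]]
    if (length(hets) >= 2L)
      out[[g]] <- cohort$variants[hets, , drop = FALSE]
  }
  out
}

#' Recessive candidate genes from a case/control cohort
#'
#' A gene enters the candidate set iff (A) every case either is
#' depth-passing homozygous-alternate at at least one variant of the gene,
#' or carries a compound-heterozygous group (two or more depth-passing
#' heterozygous variants) in the gene; and (B) no control is depth-passing
#' homozygous-alternate at any implicated variant, and no control carries a
#' compound-heterozygous group over the implicated variants. Implicated
#' variants are the union of the per-case supporting evidence (the
#' homozygous site for homozygous cases, the heterozygous group for
#' compound-heterozygous cases). Entries are sorted by gene_id, variants by
#' (chrom, pos).
#'
#' @param cohort a [cohort_genotypes()] with at least one case and one
#'   control in its sample sheet
#' @param transcripts list of [transcript_model()]
#' @param params a [filter_params()] object
#' @return object of class `CandidateSet`: list of entries, each with
#'   `gene_id`, `mode` ("homozygous", "compound_het" or "mixed"),
#'   `variants` (data.frame of implicated variants) and `per_case`
#'   (named list: sample -> list(mode, variant_ids))
#' @export
recessive_candidates <- function(cohort, transcripts,
                                 params = filter_params()) {
  roles <- cohort$samples$role
  cases <- which(roles == "case"); controls <- which(roles == "control")
  if (!length(cases) || !length(controls))
    stop("configuration error: cohort needs at least one case and one control")
  cls <- genotype_class_matrix(cohort)
  dp <- matrix(passes_depth(cohort$depth, params), nrow = nrow(cohort$variants))
  gidx <- gene_variant_index(cohort, transcripts)
  entries <- list()
  for (g in names(gidx)) {
    idx <- gidx[[g]]
    if (!length(idx)) next
    per_case <- list()
    ok <- TRUE
    informative <- 0L
    for (j in cases) {
      hom <- idx[cls[idx, j] == "hom_alt" & dp[idx, j]]
      het <- idx[cls[idx, j] == "het" & dp[idx, j]]
      usable <- idx[cls[idx, j] != "missing" & dp[idx, j]]
      sid <- cohort$samples$sample_id[j]
      if (length(hom)) {
        per_case[[sid]] <- list(mode = "homozygous", rows = hom)
        informative <- informative + 1L
      } else if (length(het) >= 2L) {
        per_case[[sid]] <- list(mode = "compound_het", rows = het)
        informative <- informative + 1L
      } else if (length(usable) || params$require_called_in_all_cases) {
        ok <- FALSE; break
      } # else: uninformative case skipped under the relaxed rule
    }
    if (!ok || informative == 0L) next
    implicated <- sort(unique(unlist(lapply(per_case, `[[`, "rows"))))
    excluded <- FALSE
    for (j in controls) {
      hom <- any(cls[implicated, j] == "hom_alt" & dp[implicated, j])
      nhet <- sum(cls[implicated, j] == "het" & dp[implicated, j])
      if (hom || nhet >= 2L) { excluded <- TRUE; break }
    }
    if (excluded) next
    modes <- unique(vapply(per_case, `[[`, "", "mode"))
    entries[[g]] <- list(
      gene_id = g,
      mode = if (length(modes) == 1L) modes else "mixed",
      variants = cohort$variants[implicated, , drop = FALSE],
      per_case = lapply(per_case, function(e) list(
        mode = e$mode, variant_ids = cohort$variants$id[e$rows])))
  }
  if (length(entries)) entries <- entries[order(names(entries))]
  structure(list(entries = unname(entries)), class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat("CandidateSet with", length(x$entries), "gene(s)\n")
  for (e in x$entries)
    cat("  ", e$gene_id, "[", e$mode, "]",
        paste(e$variants$id, collapse = ", "), "\n")
  invisible(x)
}

#' Candidate genes as a flat table
#'
#' One row per (gene, implicated variant) with per-sample genotype classes,
#' suitable for TSV export.
#'
#' @param cs a `CandidateSet` from [recessive_candidates()]
#' @param cohort the cohort the set was derived from
#' @return data.frame
#' @export
candidates_table <- function(cs, cohort) {
  stopifnot(inherits(cs, "CandidateSet"))
  cls <- genotype_class_matrix(cohort)
  rows <- list()
  for (e in cs$entries) {
    for (i in seq_len(nrow(e$variants))) {
      v <- e$variants[i, ]
      k <- match(v$id, cohort$variants$id)
      row <- data.frame(gene_id = e$gene_id, mode = e$mode, chrom = v$chrom,
                        pos = v$pos, ref = v$ref, alt = v$alt,
                        stringsAsFactors = FALSE)
      gclasses <- as.list(cls[k, ])
      names(gclasses) <- cohort$samples$sample_id
      rows[[length(rows) + 1L]] <- cbind(row, as.data.frame(gclasses,
                                                            optional = TRUE))
    }
  }
  if (!length(rows)) {
    base <- data.frame(gene_id = character(), mode = character(),
                       chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       stringsAsFactors = FALSE)
    return(base)
  }
  do.call(rbind, rows)
}

#' Per-variant homozygous-only recessive filter
#'
#' The gene-unaware form of the filter: a variant is selected iff every case
#' is depth-passing homozygous-alternate at it and no control is. Useful for
#' replicating a genome-wide pre-annotation pass without gene models.
#'
#' @param cohort a [cohort_genotypes()] object
#' @param params a [filter_params()] object
#' @return data.frame of selected variant rows
#' @export
recessive_site_filter <- function(cohort, params = filter_params()) {
  roles <- cohort$samples$role
  cases <- which(roles == "case"); controls <- which(roles == "control")
  if (!length(cases) || !length(controls))
    stop("configuration error: cohort needs at least one case and one control")
  cls <- genotype_class_matrix(cohort)
  dp <- matrix(passes_depth(cohort$depth, params), nrow = nrow(cohort$variants))
  keep <- vapply(seq_len(nrow(cohort$variants)), function(i) {
    case_ok <- cls[i, cases] == "hom_alt" & dp[i, cases]
    all_cases <- if (params$require_called_in_all_cases) all(case_ok)
                 else any(case_ok) && all(case_ok | cls[i, cases] == "missing" |
                                          !dp[i, cases])
    all_cases && !any(cls[i, controls] == "hom_alt" & dp[i, controls])
  }, logical(1))
  cohort$variants[keep, , drop = FALSE]
}
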