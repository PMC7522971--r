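#' @title Genotype tabulation, concordance summary and pipeline driver
#' @description Two-site genotype tabulation of a cohort by phenotype, a
#' recessive-model concordance summary, and an end-to-end driver running
#' simulate -> filter -> annotate -> phase -> report with one structured log
#' line per stage (variants in, depth-passing, genes tested, candidates
#' out), so the discovery funnel is inspectable.
#' @name report
NULL

genotype_string <- function(a, b, label) {
  render <- function(x) if (is.na(x)) "." else if (x == 0L) "+" else label
  g <- c(render(a), render(b))
  # canonical order: reference allele first
  paste(g[order(g != "+")], collapse = "/")
}

#' Tabulate a cohort's genotypes at two sites
#'
#' Groups samples by (phenotype, genotype pair); genotypes are rendered as
#' `+/+`, `+/<label>`, `<label>/<label>` with per-site allele labels. Rows
#' are ordered by phenotype (first appearance in the sample sheet) then
#' genotype pair.
#'
#' @param cohort a [cohort_genotypes()] object
#' @param sites character vector of 2 variant ids present in the cohort
#' @param labels allele labels per site (default c("dup", "del"))
#' @return data.frame of class `GenotypeTable`: phenotype, the two genotype
#'   columns (named `genotype_<label>`), n_samples
#' @export
genotype_table <- function(cohort, sites, labels = c("dup", "del")) {
  stopifnot(length(sites) == 2L, length(labels) == 2L)
  idx <- match(sites, cohort$variants$id)
  if (anyNA(idx)) stop("site not in cohort: ",
                       paste(sites[is.na(idx)], collapse = ", "))
  ns <- nrow(cohort$samples)
  if (ns == 0L) {
    out <- data.frame(phenotype = character(), g1 = character(),
                      g2 = character(), n_samples = integer())
  } else {
    g1 <- vapply(seq_len(ns), function(j) genotype_string(
      cohort$allele_a[idx[1], j], cohort$allele_b[idx[1], j], labels[1]), "")
    g2 <- vapply(seq_len(ns), function(j) genotype_string(
      cohort$allele_a[idx[2], j], cohort$allele_b[idx[2], j], labels[2]), "")
    phen <- cohort$samples$phenotype
    key <- paste(phen, g1, g2, sep = "\r")
    agg <- aggregate(list(n_samples = seq_len(ns)), by = list(key = key),
                     FUN = length)
    parts <- strsplit(agg$key, "\r", fixed = TRUE)
    out <- data.frame(
      phenotype = vapply(parts, `[`, "", 1L),
      g1 = vapply(parts, `[`, "", 2L),
      g2 = vapply(parts, `[`, "", 3L),
      n_samples = agg$n_samples, stringsAsFactors = FALSE)
    out <- out[order(match(out$phenotype, unique(phen)), out$g1, out$g2), ]
    rownames(out) <- NULL
  }
  names(out)[2:3] <- paste0("genotype_", labels)
  attr(out, "site_ids") <- sites
  attr(out, "labels") <- labels
  attr(out, "cohort_size") <- nrow(cohort$samples)
  class(out) <- c("GenotypeTable", "data.frame")
  out
}

mutant_allele_count <- function(g) {
  if (grepl("\\.", g)) return(NA_integer_)
  sum(strsplit(g, "/", fixed = TRUE)[[1]] != "+")
}

#' Concordance of a genotype table with a recessive model
#'
#' A sample is biallelic iff it is homozygous mutant at either site or
#' heterozygous at both (trans assumed pending phase inference). Controls
#' with exactly one mutant allele are carriers (concordant under a recessive
#' model). Discordant samples are cases lacking two mutant alleles (or with
#' a missing genotype) and controls carrying two. The four counts partition
#' the cohort.
#'
#' @param table a `GenotypeTable` from [genotype_table()]
#' @param case_phenotypes character set of phenotype labels counted as cases
#' @return list of class `ConcordanceSummary`: n_biallelic_cases,
#'   n_wildtype_controls, n_carrier_controls, n_discordant
#' @export
concordance_with_recessive_model <- function(table, case_phenotypes) {
  stopifnot(inherits(table, "GenotypeTable"))
  n_bi <- 0L; n_wt <- 0L; n_carrier <- 0L; n_disc <- 0L
  for (i in seq_len(nrow(table))) {
    a1 <- mutant_allele_count(table[[2]][i])
    a2 <- mutant_allele_count(table[[3]][i])
    n <- table$n_samples[i]
    is_case <- table$phenotype[i] %in% case_phenotypes
    biallelic <- !is.na(a1) && !is.na(a2) &&
      (a1 == 2L || a2 == 2L || (a1 == 1L && a2 == 1L))
    if (is_case) {
      if (biallelic) n_bi <- n_bi + n else n_disc <- n_disc + n
    } else {
      total <- a1 + a2
      if (biallelic) n_disc <- n_disc + n
      else if (!is.na(total) && total == 1L) n_carrier <- n_carrier + n
      else n_wt <- n_wt + n
    }
  }
  structure(list(n_biallelic_cases = n_bi, n_wildtype_controls = n_wt,
                 n_carrier_controls = n_carrier, n_discordant = n_disc),
            class = "ConcordanceSummary")
}

#' @export
print.ConcordanceSummary <- function(x, ...) {
  cat("Recessive-model concordance:\n",
      " biallelic cases:   ", x$n_biallelic_cases, "\n",
      " wild-type controls:", x$n_wildtype_controls, "\n",
      " carrier controls:  ", x$n_carrier_controls, "\n",
      " discordant:        ", x$n_discordant, "\n")
  invisible(x)
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
}

#' Run the full discovery pipeline on a simulated study
#'
#' simulate -> segregation filter -> consequence annotation of implicated
#' variants -> phase inference for causal double heterozygotes -> genotype
#' table and concordance summary at the causal sites. Logs one line per
#' stage with input/output counts.
#'
#' @param params a [simulate_params()] object
#' @param filter a [filter_params()] object
#' @param seed override of `params$seed`
#' @param outdir optional directory for TSV outputs
#' @return list: sim, candidates, annotation, phase_calls, table,
#'   concordance, recovered (logical: is the planted gene the unique
#'   candidate)
#' @export
run_pipeline <- function(params = simulate_params(),
                         filter = filter_params(),
                         seed = params$seed, outdir = NULL) {
  ref <- simulate_reference(params, seed)
  sim <- simulate_cohort(params, ref$reference, ref$transcripts, seed)
  nv <- nrow(sim$cohort$variants)
  stage_log("simulate", nv, " variants, ", nrow(sim$samples), " samples, ",
            "causal gene ", sim$truth$causal_gene_id)
  dp_pass <- sum(passes_depth(sim$cohort$depth, filter))
  stage_log("filter", "calls passing depth: ", dp_pass, "/",
            length(sim$cohort$depth))
  cands <- recessive_candidates(sim$cohort, ref$transcripts, filter)
  stage_log("filter", length(unique(vapply(ref$transcripts, `[[`, "",
                                           "gene_id"))),
            " genes tested, ", length(cands$entries), " candidate(s): ",
            paste(vapply(cands$entries, `[[`, "", "gene_id"),
                  collapse = ", "))
  impl <- unique(do.call(rbind, c(lapply(cands$entries, `[[`, "variants"),
                                  list(sim$cohort$variants[0, ]))))
  ann <- annotate_variants(impl, ref$transcripts, ref$reference)
  stage_log("annotate", nrow(ann), " (variant, transcript) consequence(s)")
  phase_calls <- list()
  if (!is.null(sim$amplicons)) {
    for (sid in unique(sim$amplicons$sample_id)) {
      obs <- sim$amplicons[sim$amplicons$sample_id == sid, , drop = FALSE]
      phase_calls[[sid]] <- infer_phase(obs, "causal_dup", "causal_del")
    }
  }
  stage_log("phase", length(phase_calls), " double-heterozygote call(s): ",
            paste(vapply(phase_calls, `[[`, "", "configuration"),
                  collapse = ", "))
  tab <- NULL; conc <- NULL
  if (all(c("causal_dup", "causal_del") %in% sim$cohort$variants$id)) {
    tab <- genotype_table(sim$cohort, c("causal_dup", "causal_del"))
    conc <- concordance_with_recessive_model(tab, "affected")
    stage_log("report", "biallelic cases ", conc$n_biallelic_cases,
              ", carrier controls ", conc$n_carrier_controls,
              ", discordant ", conc$n_discordant)
  }
  recovered <- length(cands$entries) == 1L &&
    cands$entries[[1]]$gene_id == sim$truth$causal_gene_id
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(candidates_table(cands, sim$cohort),
                file.path(outdir, "candidates.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(ann, file.path(outdir, "consequences.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(tab))
      write.table(as.data.frame(tab), file.path(outdir, "genotype_table.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(sim = sim, candidates = cands, annotation = ann,
       phase_calls = phase_calls, table = tab, concordance = conc,
       recovered = recovered)
}
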