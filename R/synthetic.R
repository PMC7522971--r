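#' @title Synthetic cohort generator
#' @description Generates a random reference genome with multi-exon genes on
#' mixed strands, then a case/control cohort in which one gene is causal
#' under a recessive model: every case carries two mutant alleles of that
#' gene (homozygous, or compound-heterozygous in trans), controls carry at
#' most one, and background variants segregate independently of phenotype
#' with a rare-skewed allele-frequency spectrum. A truth record documents
#' everything planted. The master seed is split into named substreams
#' (reference, variants, genotypes, depth, missingness, amplicons) so that
#' changing one stage's parameters does not scramble unrelated draws.
#' @name synthetic
NULL

substream_seed <- function(seed, name) {
  off <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483629)
}

random_dna <- function(n) paste(sample(DNA_ALPHABET, n, replace = TRUE),
                                collapse = "")

random_cds <- function(n_codons) {
  ok <- setdiff(names(CODON_TABLE), STOP_CODONS)
  paste0("ATG", paste(sample(ok, n_codons - 2L, replace = TRUE),
                      collapse = ""), sample(STOP_CODONS, 1L))
}

#' Simulation parameters
#'
#' Defaults emulate the study design this generator stands in for: two
#' sequenced affected genomes against six unaffected ones, deep coverage on
#' the affected animals, a single carrier expected among ~27 controls
#' (carrier rate 0.04), complete genotyping (no missingness), and a
#' rare-skewed background allele-frequency spectrum (Beta(0.3, 8)).
#'
#' @param n_genes number of genes on the simulated contig
#' @param n_background_variants background SNVs independent of phenotype
#' @param n_cases,n_controls cohort composition (>= 1 each)
#' @param causal_config "hom_del", "hom_dup", "compound_het" or
#'   "mixed_per_case" (each case gets a random one of the three)
#' @param carrier_rate_in_controls probability a control carries one mutant
#'   allele
#' @param depth_mean Poisson mean of simulated DP
#' @param missing_rate per-call masking probability
#' @param seed master seed
#' @return list of class `SimulationParams`
#' @export
simulate_params <- function(n_genes = 20L, n_background_variants = 60L,
                            n_cases = 2L, n_controls = 6L,
                            causal_config = "mixed_per_case",
                            carrier_rate_in_controls = 0.04,
                            depth_mean = 20, missing_rate = 0,
                            seed = 1L) {
  causal_config <- match.arg(causal_config,
                             c("hom_del", "hom_dup", "compound_het",
                               "mixed_per_case"))
  stopifnot(n_genes >= 0L, n_background_variants >= 0L,
            n_cases >= 1L, n_controls >= 1L,
            carrier_rate_in_controls >= 0, carrier_rate_in_controls <= 1,
            missing_rate >= 0, missing_rate <= 1, depth_mean > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_background_variants = as.integer(n_background_variants),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 causal_config = causal_config,
                 carrier_rate_in_controls = carrier_rate_in_controls,
                 depth_mean = depth_mean, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

#' Simulate a reference genome with gene models
#'
#' One contig carrying `n_genes` multi-exon genes on mixed strands, each with
#' a valid CDS (ATG start, stop end, length divisible by 3, no internal
#' stop) and a 150-nt 3'UTR in its last exon. Deterministic given the seed.
#'
#' @param params a [simulate_params()] object
#' @param seed override of `params$seed`
#' @return list(reference = [reference_sequences()], transcripts = list of
#'   [transcript_model()])
#' @export
simulate_reference <- function(params = simulate_params(),
                               seed = params$seed) {
  set.seed(substream_seed(seed, "reference"))
  utr3_len <- 150L
  contig <- "contig_1"
  parts <- character(); cursor <- 0L
  transcripts <- list()
  gap <- function() random_dna(sample(200:400, 1L))
  g0 <- gap(); parts <- g0; cursor <- nchar(g0)
  for (g in seq_len(params$n_genes)) {
    n_codons <- sample(90:180, 1L)
    cds <- random_cds(n_codons)
    utr3 <- random_dna(utr3_len)
    n_ex <- sample(2:4, 1L)
    # split CDS into n_ex chunks of >= 10 nt
    repeat {
      cuts <- sort(sample(seq(10L, nchar(cds) - 10L), n_ex - 1L))
      lens <- diff(c(0L, cuts, nchar(cds)))
      if (all(lens >= 10L)) break
    }
    strand <- sample(c("+", "-"), 1L)
    # transcript-plus local layout: exon chunks separated by introns,
    # 3'UTR appended to the last exon
    local_seq <- ""; lpos <- 0L
    ex <- list(); cd <- list()
    for (i in seq_along(lens)) {
      chunk_start <- lpos
      chunk <- substr(cds, sum(lens[seq_len(i - 1L)]) + 1L,
                      sum(lens[seq_len(i)]))
      local_seq <- paste0(local_seq, chunk); lpos <- lpos + lens[i]
      cd[[i]] <- c(chunk_start, lpos)
      if (i == length(lens)) {
        local_seq <- paste0(local_seq, utr3); lpos <- lpos + utr3_len
        ex[[i]] <- c(chunk_start, lpos)
      } else {
        ex[[i]] <- c(chunk_start, lpos)
        intron <- random_dna(sample(50:150, 1L))
        local_seq <- paste0(local_seq, intron); lpos <- lpos + nchar(intron)
      }
    }
    Lg <- nchar(local_seq)
    if (strand == "-") {
      local_seq <- dna_revcomp(local_seq)
      mirror <- function(iv) c(Lg - iv[2], Lg - iv[1])
      ex <- lapply(ex, mirror); cd <- lapply(cd, mirror)
    }
    to_df <- function(lst, base) {
      d <- do.call(rbind, lst)
      data.frame(start = d[, 1] + base, end = d[, 2] + base)
    }
    gene_id <- sprintf("gene_%02d", g)
    transcripts[[paste0(gene_id, ".t1")]] <- transcript_model(
      gene_id, paste0(gene_id, ".t1"), contig, strand,
      to_df(ex, cursor), to_df(cd, cursor))
    parts <- c(parts, local_seq, gap())
    cursor <- cursor + Lg + nchar(parts[length(parts)])
  }
  ref <- reference_sequences(setNames(list(paste(parts, collapse = "")),
                                      contig))
  for (t in transcripts) validate_transcript(t, ref)
  list(reference = ref, transcripts = transcripts)
}

# 0-based genomic position of a 1-based CDS coordinate
genomic_pos_of_cds <- function(t, k) {
  L <- cds_length(t)
  i0 <- if (t$strand == "+") k - 1L else L - k
  offs <- cumsum(c(0L, t$cds$end - t$cds$start))
  for (i in seq_len(nrow(t$cds))) {
    if (i0 < offs[i + 1L]) return(t$cds$start[i] + (i0 - offs[i]))
  }
  stop("CDS coordinate out of range: ", k)
}

# VCF-style (1-based pos, ref, alt) for a deletion of CDS s..e and for a
# duplication of CDS s..e, on either strand, anchored on the left genomic base
causal_variant_records <- function(t, ref, del_range, dup_range) {
  seq <- ref_seq(ref, t$chrom)
  base_at <- function(g0) substr(seq, g0 + 1L, g0 + 1L)
  span_of <- function(rng) {
    g <- vapply(rng[1]:rng[2], function(k) genomic_pos_of_cds(t, k),
                integer(1))
    c(min(g), max(g))
  }
  # deletion: remove genomic span; anchor at preceding base
  ds <- span_of(del_range)
  del_pos0 <- ds[1] - 1L
  del_ref <- substr(seq, del_pos0 + 1L, ds[2] + 1L)
  del <- list(pos = del_pos0 + 1L, ref = del_ref, alt = base_at(del_pos0))
  # duplication: insert a copy of the segment 3' of itself (transcript
  # sense); in genomic terms insert the segment next to itself
  us <- span_of(dup_range)
  seg <- substr(seq, us[1] + 1L, us[2] + 1L)
  if (t$strand == "+") {
    ins_pos0 <- us[2]          # anchor at last duplicated base
    dup <- list(pos = ins_pos0 + 1L, ref = base_at(ins_pos0),
                alt = paste0(base_at(ins_pos0), seg))
  } else {
    ins_pos0 <- us[1] - 1L     # insertion left of the segment, anchored
    dup <- list(pos = ins_pos0 + 1L, ref = base_at(ins_pos0),
                alt = paste0(base_at(ins_pos0), seg))
  }
  list(del = del, dup = dup)
}

#' Simulate a case/control cohort with a planted recessive gene
#'
#' One gene is chosen causal and given a 16-bp frameshift deletion and a
#' 2-bp duplication in its CDS (the two mutant alleles). Every case receives
#' two mutant alleles per `causal_config`; compound-heterozygous cases carry
#' the two variants in trans (recorded in the truth record, and observable
#' through the simulated allele-specific amplicons — the discovery filter
#' itself never sees phase). Controls carry at most one mutant allele, at
#' rate `carrier_rate_in_controls`. Background SNVs get genotypes
#' independent of case status from per-variant allele frequencies drawn from
#' Beta(0.3, 8). DP is Poisson(`depth_mean`); calls are masked missing at
#' `missing_rate` (masking never alters alleles).
#'
#' @param params a [simulate_params()] object
#' @param reference,transcripts from [simulate_reference()]
#' @param seed override of `params$seed`
#' @return list: `cohort` (masked), `cohort_unmasked`, `samples`, `truth`
#'   (causal gene/variants, per-sample planted genotypes and phase),
#'   `amplicons` (observations for each causal double heterozygote)
#' @export
simulate_cohort <- function(params = simulate_params(), reference,
                            transcripts, seed = params$seed) {
  n <- params$n_cases + params$n_controls
  samples <- sample_sheet(
    c(sprintf("case_%02d", seq_len(params$n_cases)),
      sprintf("control_%02d", seq_len(params$n_controls))),
    phenotype = rep(c("affected", "unaffected"),
                    c(params$n_cases, params$n_controls)),
    role = rep(c("case", "control"), c(params$n_cases, params$n_controls)))
  contig <- names(reference)[1]
  clen <- nchar(ref_seq(reference, contig))

  # --- causal variants -------------------------------------------------
  set.seed(substream_seed(seed, "variants"))
  eligible <- Filter(function(t) cds_length(t) >= 120L &&
                       any(t$cds$end - t$cds$start >= 60L), transcripts)
  if (params$n_genes > 0L && !length(eligible))
    stop("parameter error: no gene has a CDS long enough for two causal sites")
  causal <- NULL; causal_recs <- NULL
  if (length(eligible)) {
    causal <- eligible[[sample(length(eligible), 1L)]]
    L <- cds_length(causal)
    # deletion in the 3' half, duplication in the 5' half, inside one exon
    offs <- cumsum(c(0L, causal$cds$end - causal$cds$start))
    # CDS-coordinate range covered by each genomic CDS interval (strand-aware)
    iv_cds <- lapply(seq_len(nrow(causal$cds)), function(i) {
      if (causal$strand == "+") c(offs[i] + 1L, offs[i + 1L])
      else c(L - offs[i + 1L] + 1L, L - offs[i])
    })
    pick_in_exon <- function(width, lo, hi) {
      # returns CDS range of `width` inside one CDS interval, within [lo,hi]
      for (i in sample(nrow(causal$cds))) {
        s0 <- iv_cds[[i]][1]; e0 <- iv_cds[[i]][2]
        a <- max(s0 + 1L, lo); b <- min(e0 - width, hi)
        if (b >= a) {
          s <- sample(a:b, 1L)
          return(c(s, s + width - 1L))
        }
      }
      stop("parameter error: CDS too short to place causal variants")
    }
    dup_range <- pick_in_exon(2L, 4L, max(4L, L %/% 3L))
    del_range <- pick_in_exon(16L, min(L - 30L, L %/% 2L), L - 20L)
    causal_recs <- causal_variant_records(causal, reference,
                                          del_range, dup_range)
  }

  # --- background variants --------------------------------------------
  nb <- params$n_background_variants
  blocked <- integer()
  if (!is.null(causal_recs))
    blocked <- unique(unlist(lapply(causal_recs, function(r)
      seq(r$pos, r$pos + nchar(r$ref) - 1L))))
  avail <- setdiff(seq_len(clen), blocked)
  bpos <- sort(sample(avail, min(nb, length(avail))))
  cseq <- ref_seq(reference, contig)
  bref <- substring(cseq, bpos, bpos)
  balt <- vapply(bref, function(b) sample(setdiff(DNA_ALPHABET, b), 1L), "")
  maf <- rbeta(length(bpos), 0.3, 8)

  vt <- variant_table(
    chrom = rep(contig, length(bpos)), pos = bpos, ref = bref, alt = balt,
    id = sprintf("bg_%03d", seq_along(bpos)))
  if (!is.null(causal_recs)) {
    vt <- rbind(vt, variant_table(
      chrom = c(contig, contig),
      pos = c(causal_recs$del$pos, causal_recs$dup$pos),
      ref = c(causal_recs$del$ref, causal_recs$dup$ref),
      alt = c(causal_recs$del$alt, causal_recs$dup$alt),
      id = c("causal_del", "causal_dup")))
  }

  # --- genotypes -------------------------------------------------------
  set.seed(substream_seed(seed, "genotypes"))
  nv <- nrow(vt)
  aa <- matrix(0L, nv, n); ab <- matrix(0L, nv, n)
  is_bg <- grepl("^bg_", vt$id)
  for (i in which(is_bg)) {
    p <- maf[match(vt$id[i], sprintf("bg_%03d", seq_along(bpos)))]
    aa[i, ] <- rbinom(n, 1L, p)
    ab[i, ] <- rbinom(n, 1L, p)
  }
  i_del <- match("causal_del", vt$id); i_dup <- match("causal_dup", vt$id)
  planted <- list(); amp_truth <- character()
  case_cols <- seq_len(params$n_cases)
  configs <- if (params$causal_config == "mixed_per_case") {
    sample(c("hom_del", "hom_dup", "compound_het"), params$n_cases,
           replace = TRUE)
  } else rep(params$causal_config, params$n_cases)
  if (!is.null(causal_recs)) {
    for (k in case_cols) {
      sid <- samples$sample_id[k]
      if (configs[k] == "hom_del") {
        aa[i_del, k] <- 1L; ab[i_del, k] <- 1L
        planted[[sid]] <- data.frame(sample_id = sid,
                                     variant_id = "causal_del",
                                     genotype = "hom_alt", phase = NA)
      } else if (configs[k] == "hom_dup") {
        aa[i_dup, k] <- 1L; ab[i_dup, k] <- 1L
        planted[[sid]] <- data.frame(sample_id = sid,
                                     variant_id = "causal_dup",
                                     genotype = "hom_alt", phase = NA)
      } else {
        aa[i_del, k] <- 1L; ab[i_del, k] <- 0L  # del on haplotype A
        aa[i_dup, k] <- 0L; ab[i_dup, k] <- 1L  # dup on haplotype B: trans
        planted[[sid]] <- data.frame(
          sample_id = sid, variant_id = c("causal_del", "causal_dup"),
          genotype = "het", phase = "trans")
        amp_truth <- c(amp_truth, sid)
      }
    }
    for (k in params$n_cases + seq_len(params$n_controls)) {
      if (runif(1) < params$carrier_rate_in_controls) {
        i <- sample(c(i_del, i_dup), 1L)
        aa[i, k] <- 0L; ab[i, k] <- 1L
        sid <- samples$sample_id[k]
        planted[[sid]] <- data.frame(
          sample_id = sid,
          variant_id = vt$id[i], genotype = "het", phase = NA)
      }
    }
  }

  set.seed(substream_seed(seed, "depth"))
  dp <- matrix(rpois(nv * n, params$depth_mean), nv, n)

  unmasked <- cohort_genotypes(vt, samples, aa, ab, depth = dp)
  set.seed(substream_seed(seed, "missingness"))
  mask <- matrix(runif(nv * n) < params$missing_rate, nv, n)
  aam <- unmasked$allele_a; abm <- unmasked$allele_b
  aam[mask] <- NA_integer_; abm[mask] <- NA_integer_
  cohort <- cohort_genotypes(unmasked$variants, samples, aam, abm,
                             depth = unmasked$depth)

  set.seed(substream_seed(seed, "amplicons"))
  amps <- NULL
  for (sid in amp_truth) {
    a <- simulate_amplicons("trans", site_a = "causal_dup",
                            site_b = "causal_del")
    a$sample_id <- sid
    amps <- rbind(amps, a)
  }

  truth <- list(
    causal_gene_id = if (is.null(causal)) NA_character_ else causal$gene_id,
    causal_variant_ids = if (is.null(causal)) character()
                         else c("causal_del", "causal_dup"),
    case_configs = if (is.null(causal)) character()
                   else setNames(configs, samples$sample_id[case_cols]),
    planted = if (length(planted)) do.call(rbind, unname(planted))
              else data.frame(sample_id = character(),
                              variant_id = character(),
                              genotype = character(), phase = character()))
  list(cohort = cohort, cohort_unmasked = unmasked, samples = samples,
       truth = truth, amplicons = amps)
}

#' Simulate a full study and write it to disk
#'
#' Writes ref.fa, genes.gff3, cohort.vcf, samples.tsv, truth.json and
#' amplicons.tsv into `outdir`.
#'
#' @param params a [simulate_params()] object
#' @param outdir output directory (created if needed)
#' @param seed override of `params$seed`
#' @return invisibly, named list of file paths plus the in-memory simulation
#' @export
simulate_study <- function(params = simulate_params(), outdir,
                           seed = params$seed) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(params, seed)
  sim <- simulate_cohort(params, ref$reference, ref$transcripts, seed)
  paths <- list(
    fasta = file.path(outdir, "ref.fa"),
    gff3 = file.path(outdir, "genes.gff3"),
    vcf = file.path(outdir, "cohort.vcf"),
    samples = file.path(outdir, "samples.tsv"),
    truth = file.path(outdir, "truth.json"),
    amplicons = file.path(outdir, "amplicons.tsv"))
  write_fasta(ref$reference, paths$fasta)
  write_gff3(ref$transcripts, paths$gff3)
  write_vcf(sim$cohort, paths$vcf)
  write_sample_sheet(sim$samples, paths$samples)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE,
                       dataframe = "rows", na = "null")
  if (!is.null(sim$amplicons))
    write.table(sim$amplicons, paths$amplicons, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(c(paths, list(reference = ref$reference,
                          transcripts = ref$transcripts, sim = sim)))
}
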