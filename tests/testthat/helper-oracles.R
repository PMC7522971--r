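# Shared fixtures and independent oracles.

# --- toy single/multi-exon transcripts on explicit sequences ---------------

# plus-strand toy: 10 nt leader, CDS "ATGAAATAA" at genomic 11..19 (1-based)
toy_plus <- function() {
  seq <- paste0("GGGGGGGGGG", "ATGAAATAA", "CCCCCCCCCC")
  ref <- reference_sequences(setNames(list(seq), "chrT"))
  t <- transcript_model("gT", "gT.t1", "chrT", "+",
                        data.frame(start = 10, end = 29),
                        data.frame(start = 10, end = 19))
  list(ref = ref, t = t)
}

# mirror of an arbitrary plus-strand layout: reverse-complement the contig
# and reflect all intervals; the spliced CDS must be identical
mirror_minus <- function(ref, t) {
  seq <- unclass(ref)[[t$chrom]]
  L <- nchar(seq)
  rseq <- minkmap:::dna_revcomp(seq)
  flip <- function(d) {
    out <- data.frame(start = L - d$end, end = L - d$start)
    out[order(out$start), ]
  }
  list(ref = reference_sequences(setNames(list(rseq), t$chrom)),
       t = transcript_model(t$gene_id, t$transcript_id, t$chrom,
                            if (t$strand == "+") "-" else "+",
                            flip(t$exons), flip(t$cds)))
}

# mirror a variant (1-based pos, ref, alt strings) onto the flipped contig
mirror_variant <- function(v, contig_len) {
  rc <- minkmap:::dna_revcomp
  data.frame(chrom = v$chrom,
             pos = contig_len - (v$pos + nchar(v$ref) - 1L) + 1L,
             ref = rc(v$ref), alt = rc(v$alt),
             id = v$id, stringsAsFactors = FALSE)
}

# --- random cohort generator ----------------------------------------------

random_cohort <- function(nv = 5, ns = 4, seed = 1, indels = TRUE,
                          roles = NULL, contig = "c1") {
  set.seed(seed)
  pos <- sort(sample(50:5000, nv))
  ref <- character(nv); alt <- character(nv)
  for (i in seq_len(nv)) {
    if (indels && runif(1) < 0.3) {
      ref[i] <- paste(sample(c("A", "C", "G", "T"), sample(2:4, 1), TRUE),
                      collapse = "")
      alt[i] <- substr(ref[i], 1, 1)
    } else {
      ref[i] <- sample(c("A", "C", "G", "T"), 1)
      alt[i] <- sample(setdiff(c("A", "C", "G", "T"), ref[i]), 1)
    }
  }
  vt <- variant_table(rep(contig, nv), pos, ref, alt)
  if (is.null(roles)) roles <- sample(c("case", "control"), ns, TRUE)
  sm <- sample_sheet(sprintf("s%02d", seq_len(ns)),
                     phenotype = sample(c("affected", "unaffected"), ns, TRUE),
                     role = roles)
  aa <- matrix(sample(c(0L, 1L, NA), nv * ns, TRUE, prob = c(.5, .4, .1)),
               nrow = nv, ncol = ns)
  ab <- matrix(sample(c(0L, 1L, NA), nv * ns, TRUE, prob = c(.5, .4, .1)),
               nrow = nv, ncol = ns)
  dp <- matrix(sample(c(NA, 1L, 2L, 3L, 8L, 30L), nv * ns, TRUE),
               nrow = nv, ncol = ns)
  ph <- matrix(sample(c(TRUE, FALSE), nv * ns, TRUE, prob = c(.1, .9)),
               nrow = nv, ncol = ns)
  cohort_genotypes(vt, sm, aa, ab, dp, ph)
}

# --- independent brute-force segregation oracle ----------------------------
# A direct, loop-wise transcription of the selection rule, independent of the
# package's matrix code paths.
oracle_recessive <- function(cohort, gene_spans, min_dp = 2) {
  v <- cohort$variants; s <- cohort$samples
  cls <- function(i, j) {
    a <- cohort$allele_a[i, j]; b <- cohort$allele_b[i, j]
    if (is.na(a) || is.na(b)) return("missing")
    if (a + b == 0) "hom_ref" else if (a + b == 1) "het" else "hom_alt"
  }
  dpok <- function(i, j) {
    d <- cohort$depth[i, j]; !is.na(d) && d > min_dp
  }
  out <- character()
  for (g in names(gene_spans)) {
    sp <- gene_spans[[g]]
    vidx <- which(v$chrom == sp$chrom & (v$pos - 1) >= sp$lo &
                  (v$pos - 1) < sp$hi)
    if (!length(vidx)) next
    implicated <- integer(); all_ok <- TRUE
    for (j in which(s$role == "case")) {
      hom <- vidx[vapply(vidx, function(i) cls(i, j) == "hom_alt" &&
                           dpok(i, j), TRUE)]
      het <- vidx[vapply(vidx, function(i) cls(i, j) == "het" &&
                           dpok(i, j), TRUE)]
      if (length(hom)) implicated <- union(implicated, hom)
      else if (length(het) >= 2) implicated <- union(implicated, het)
      else { all_ok <- FALSE; break }
    }
    if (!all_ok) next
    excl <- FALSE
    for (j in which(s$role == "control")) {
      nh <- 0
      for (i in implicated) {
        if (cls(i, j) == "hom_alt" && dpok(i, j)) { excl <- TRUE; break }
        if (cls(i, j) == "het" && dpok(i, j)) nh <- nh + 1
      }
      if (nh >= 2) excl <- TRUE
      if (excl) break
    }
    if (!excl) out <- c(out, g)
  }
  sort(out)
}

spans_of <- function(transcripts) {
  out <- list()
  for (t in transcripts) {
    sp <- list(chrom = t$chrom, lo = min(t$exons$start),
               hi = max(t$exons$end))
    cur <- out[[t$gene_id]]
    if (!is.null(cur)) {
      sp$lo <- min(sp$lo, cur$lo); sp$hi <- max(sp$hi, cur$hi)
    }
    out[[t$gene_id]] <- sp
  }
  out
}

# span-only "transcripts" for filter tests that never touch the CDS
span_gene <- function(gene_id, chrom, lo, hi) {
  transcript_model(gene_id, paste0(gene_id, ".t"), chrom, "+",
                   data.frame(start = lo, end = hi),
                   data.frame(start = lo, end = hi))
}

# --- independent consequence oracle (Biostrings translation) ---------------
oracle_consequence <- function(v, cds, utr3 = "") {
  # splice the edit with plain string surgery, then translate with Biostrings
  L <- nchar(cds)
  pre <- function(k) substr(cds, 1, k)
  post <- function(k) substr(cds, k, L)
  m <- switch(v$kind,
    substitution = paste0(pre(v$cds_start - 1), v$inserted_seq,
                          post(v$cds_start + 1)),
    deletion = paste0(pre(v$cds_start - 1), post(v$cds_end + 1)),
    duplication = {
      seg <- substr(cds, v$cds_start, v$cds_end)
      paste0(pre(v$cds_end), seg, post(v$cds_end + 1))
    },
    insertion = paste0(pre(v$cds_start), v$inserted_seq,
                       post(v$cds_start + 1)),
    delins = paste0(pre(v$cds_start - 1), v$inserted_seq,
                    post(v$cds_end + 1)))
  full <- paste0(m, utr3)
  ncod <- nchar(full) %/% 3
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(full, 1, ncod * 3)),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  list(mutant = m,
       mut_stop = if (stop_at > 0) as.integer(stop_at) else NA_integer_,
       wt_stop = L %/% 3,
       net = nchar(m) - L)
}

random_coding_variant <- function(L) {
  kind <- sample(c("substitution", "deletion", "duplication", "insertion",
                   "delins"), 1)
  rseq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  if (kind == "substitution") {
    p <- sample(L, 1)
    NULL # caller fills ref from cds
    list(kind = kind, s = p, e = p, ins = rseq(1))
  } else if (kind == "deletion") {
    s <- sample(L - 1, 1); e <- min(L, s + sample(0:5, 1))
    list(kind = kind, s = s, e = e, ins = "")
  } else if (kind == "duplication") {
    s <- sample(L - 1, 1); e <- min(L, s + sample(0:3, 1))
    list(kind = kind, s = s, e = e, ins = "")
  } else if (kind == "insertion") {
    p <- sample(L - 1, 1)
    list(kind = kind, s = p, e = p, ins = rseq(sample(1:5, 1)))
  } else {
    s <- sample(L - 1, 1); e <- min(L, s + sample(0:4, 1))
    list(kind = kind, s = s, e = e, ins = rseq(sample(1:5, 1)))
  }
}

random_cds_string <- function(n_codons) {
  ok <- setdiff(names(minkmap:::CODON_TABLE), c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(ok, n_codons - 2, TRUE), collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1))
}
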