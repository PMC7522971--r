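#' @title Packaged fixtures: surrogate RAB38 CDS and the genotyping table
#' @description Two fixed, committed fixtures. (1) A synthetic surrogate for
#' the RAB38 coding sequence: 633 coding nucleotides plus a terminal TAA
#' (211 residues, stop codon index 212), constructed so that the 16-bp
#' deletion at c.574-589 frameshifts at codon 192 and reads through the
#' reference stop into the 3'UTR (first mutant stop at codon 277), and the
#' 2-bp duplication at c.20-21 (sequence CT) frameshifts at codon 8 with a
#' premature stop at codon 15. It is a surrogate with the published stop
#' arithmetic, not the real mink transcript. (2) The published genotyping
#' table of 35 animals at the two mutation sites, transcribed row by row.
#' @name fixtures
NULL

RAB38_SURROGATE_CDS <- paste0(
  "ATGGAACATGAAGGTGTACCTAGTGACGGAAATAGACTACTGACCAAGACAAAAGTAGATCGAAATGGAC",
  "TCTTTAGCCCTGCCGGGACGCATCGTGTATACGAATGTAGCGAAATGGGGAACAATCAAGCAAGGATGTT",
  "ACCAATCGCACCGCAGTTAGGCGCTGTCCCGTACATCACCACGCATCGGGAGAGCGAGCGCTCGTCTAAG",
  "TTTCGTCGAAACGGTTGGCAGAACTATGCCGGCAAACCTTTGGGCCCCCGACGGTCTTTTAATAGATTCC",
  "CGACAAAACGGTCCAACCGGCTCTCCCCGTTAGTGTCTCCCGGGGTCTCTAGCACCGGAGCAGCCGGTCC",
  "TACCTCTATCGTCAAGGATTCCGAGGGGACAACTTATACTATCAGGGTGGGCTGGGACAGGCCAAGGTTG",
  "GGCCCAACCGTAGGCGTCCAAGACGTAATGATTGGCTCACTATACCCACGTCCTTCCGTGTCGTGCATCT",
  "TTAGCCTGCACTCAACCCGTTTCTGTGTGAGTCCCAACGCATCGGTAATAGGGTATCACCAGTTTGATGG",
  "TGTGGGACTTGTGGTTAATAGTAGGCATCACCTTGGACACTTTAATATTCTTATCCAAGGGCCTGAGTGT",
  "CTATAA")

RAB38_SURROGATE_UTR3 <- paste0(
  "TCGCCTTCCAGCGATAAATGTAGCATGCGTTTACAACCTATCTTGGAACTCGCCACTACACCCATCCTCT",
  "TGCCACCTCTCAAGGCTAGGGTATTGGTTATTTACCTTTAATAAAGCGTTTGTGGACGTTTTGCGATCTA",
  "AGAGGGCTTCCCCAAGAAAGTTCAGCGTGACGTGGGTGCAGTTGCAAGACTGTTCCCGCGAAGGCAGGTA",
  "ATACCGCCCCTATGGAGGGAAACGCCTCAA")

#' Surrogate RAB38 CDS fixture
#'
#' @return list: `cds` (636-nt string, 633 coding nt + TAA), `utr3` (240-nt
#'   string), `sites` (del_site = CDS 574..589, dup_site = CDS 20..21)
#' @export
rab38_surrogate_fixture <- function() {
  list(cds = RAB38_SURROGATE_CDS, utr3 = RAB38_SURROGATE_UTR3,
       sites = list(del_site = c(574L, 589L), dup_site = c(20L, 21L)))
}

#' Surrogate RAB38 gene in genomic context
#'
#' Embeds the surrogate CDS in a three-exon minus-strand gene (the
#' duplication site in exon 1, the deletion site in exon 3, mirroring the
#' published gene structure and orientation) on a synthetic contig, and
#' derives the two mutations as anchored VCF-style variant records.
#'
#' @return list: `reference`, `transcripts` (one model, gene_id "RAB38S"),
#'   `variants` (2-row [variant_table()]: causal_dup, causal_del)
#' @export
rab38_surrogate_gene <- function() {
  fx <- rab38_surrogate_fixture()
  cds <- fx$cds; utr3 <- fx$utr3
  # transcript-plus local layout: exon1 = cds 1..100, exon2 = cds 101..500,
  # exon3 = cds 501..636 + 3'UTR; introns of 150 and 120 nt
  set.seed(894721L)
  i1 <- random_dna(150L); i2 <- random_dna(120L)
  up <- random_dna(100L); down <- random_dna(100L)
  local_seq <- paste0(substr(cds, 1, 100), i1, substr(cds, 101, 500), i2,
                      substr(cds, 501, 636), utr3)
  ex <- list(c(0L, 100L), c(250L, 650L), c(770L, 906L + nchar(utr3)))
  cd <- list(c(0L, 100L), c(250L, 650L), c(770L, 906L))
  Lg <- nchar(local_seq)
  # minus strand: mirror the local layout
  gseq <- paste0(up, dna_revcomp(local_seq), down)
  base <- nchar(up)
  mirror <- function(iv) c(base + Lg - iv[2], base + Lg - iv[1])
  to_df <- function(lst) {
    d <- do.call(rbind, lapply(lst, mirror))
    data.frame(start = d[, 1], end = d[, 2])
  }
  ref <- reference_sequences(setNames(list(gseq), "scaffold_7"))
  t <- transcript_model("RAB38S", "RAB38S.t1", "scaffold_7", "-",
                        to_df(ex), to_df(cd))
  validate_transcript(t, ref)
  recs <- causal_variant_records(t, ref, del_range = c(574L, 589L),
                                 dup_range = c(20L, 21L))
  variants <- variant_table(
    chrom = rep("scaffold_7", 2L),
    pos = c(recs$dup$pos, recs$del$pos),
    ref = c(recs$dup$ref, recs$del$ref),
    alt = c(recs$dup$alt, recs$del$alt),
    id = c("causal_dup", "causal_del"))
  list(reference = ref, transcripts = list(RAB38S.t1 = t),
       variants = variants)
}

#' The packaged genotyping-table fixture
#'
#' An exact transcription of the published two-site genotyping results over
#' 35 animals: the affected phenotypes (Moyle, Lavender, Violet) carry two
#' mutant alleles each (homozygous at one site or heterozygous at both),
#' 26 of the 27 remaining animals are wild type at both sites, and a single
#' royal pastel animal is heterozygous for the deletion. Genotypes are laid
#' over the surrogate gene's two variant sites with uniform deep coverage
#' (the published genotyping is complete).
#'
#' @return list: `cohort` ([cohort_genotypes()] over 2 sites x 35 samples),
#'   `samples`, `reference`, `transcripts`, `variants` (dup, del sites)
#' @export
table1_fixture <- function() {
  g <- rab38_surrogate_gene()
  rows <- list(
    # phenotype, role, genotype at dup site, genotype at del site, n
    list("Moyle",               "case",    "0/0", "1/1", 1L),
    list("Moyle",               "case",    "0/1", "0/1", 2L),
    list("Lavender",            "case",    "0/1", "0/1", 1L),
    list("Violet",              "case",    "1/1", "0/0", 1L),
    list("Violet",              "case",    "0/1", "0/1", 1L),
    list("Violet",              "case",    "0/0", "1/1", 2L),
    list("Standard dark brown", "control", "0/0", "0/0", 17L),
    list("Silverblue",          "control", "0/0", "0/0", 2L),
    list("Shadow silverblue",   "control", "0/0", "0/0", 1L),
    list("Royal pastel",        "control", "0/0", "0/0", 5L),
    list("Royal pastel",        "control", "0/0", "0/1", 1L),
    list("Cross sapphire",      "control", "0/0", "0/0", 1L))
  phen <- character(); role <- character(); gdup <- character()
  gdel <- character()
  for (r in rows) {
    phen <- c(phen, rep(r[[1]], r[[5]]))
    role <- c(role, rep(r[[2]], r[[5]]))
    gdup <- c(gdup, rep(r[[3]], r[[5]]))
    gdel <- c(gdel, rep(r[[4]], r[[5]]))
  }
  ids <- sprintf("mink_%02d", seq_along(phen))
  samples <- sample_sheet(ids, phenotype = phen, role = role)
  split_gt <- function(g, k) as.integer(substr(g, k, k))
  # variant order in the cohort follows (chrom, pos): build matrices in the
  # variants' table order (dup first, del second) and let sorting reorder
  aa <- rbind(vapply(gdup, split_gt, integer(1), k = 1),
              vapply(gdel, split_gt, integer(1), k = 1))
  ab <- rbind(vapply(gdup, split_gt, integer(1), k = 3),
              vapply(gdel, split_gt, integer(1), k = 3))
  dp <- matrix(30L, 2L, length(ids))
  cohort <- cohort_genotypes(g$variants, samples, aa, ab, depth = dp)
  list(cohort = cohort, samples = samples, reference = g$reference,
       transcripts = g$transcripts, variants = g$variants)
}
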