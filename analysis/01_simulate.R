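#!/usr/bin/env Rscript
# Stage 1: simulate a study. One contig, 20 genes, a planted recessive
# causal gene (16-bp frameshift deletion + 2-bp duplication), 2 affected and
# 6 unaffected genomes. Writes FASTA/GFF3/VCF/sample sheet/truth/amplicons.

suppressMessages(library(minkmap))

seed <- 7L
outdir <- "results/sim"
p <- simulate_params(seed = seed)

out <- simulate_study(p, outdir)
sim <- out$sim

cat("Simulated cohort written to", outdir, "\n")
cat("  contig length:", nchar(out$reference[[1]]), "nt;",
    length(out$transcripts), "genes\n")
cat("  variants:", nrow(sim$cohort$variants),
    "(", sum(grepl("^bg_", sim$cohort$variants$id)), "background,",
    sum(grepl("^causal_", sim$cohort$variants$id)), "causal )\n")
cat("  causal gene:", sim$truth$causal_gene_id, "\n")
cat("  case configurations:",
    paste(names(sim$truth$case_configs), sim$truth$case_configs,
          sep = "=", collapse = ", "), "\n")
cat("  carrier controls:",
    sum(grepl("^control", sim$truth$planted$sample_id)), "\n")
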