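---
title: "Recessive gene mapping without pedigrees: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recessive gene mapping without pedigrees: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minkmap)
```

# The problem and the model

A recessive Mendelian phenotype expresses only when both copies of the
causal gene are mutant: homozygous for one damaging allele, or compound
heterozygous — two different damaging alleles, one per homologous
chromosome (*in trans*). With only a handful of sequenced genomes and no
pedigree, the discovery argument is purely segregational: a causal gene
must be biallelically mutant in **every** affected individual and in **no**
unaffected one.

`recessive_candidates()` operationalises this. For each gene (the span from
its first to last exon, so intronic variants are not silently dropped):

* **Rule A (cases).** Every case must either be homozygous-alternate at at
  least one variant of the gene, or heterozygous at two or more variants of
  the gene. Only calls with depth `DP > min_depth_exclusive` count
  (default 2, i.e. DP ≥ 3) — a shallow genotype is treated as no
  information, not as reference.
* **Rule B (controls).** No control may be homozygous-alternate at any
  implicated variant, nor carry two or more heterozygous implicated
  variants of the gene. Implicated variants are the union of the per-case
  supporting evidence: the homozygous site(s) for homozygous cases, the
  full heterozygous group for compound-heterozygous cases.

Three asymmetries are deliberate:

* **Controls exclude only through affirmative evidence.** A missing or
  low-depth control genotype never removes a candidate. Unaffected genomes
  are often sequenced at a fraction of the cases' depth; requiring
  affirmative exclusion keeps a true gene alive through control no-calls.
* **Heterozygous carriers never exclude.** One mutant allele is compatible
  with a recessive model; carriers among unaffected animals are expected.
* **Phase is not consulted at discovery.** Any two heterozygous variants in
  a gene count as a putative compound heterozygote; resolving *cis* (same
  chromosome, one intact copy remains) versus *trans* is deferred to the
  phase module, mirroring how such studies confirm compound heterozygosity
  experimentally rather than from caller output.

Missing genotypes in *cases* are a policy choice
(`require_called_in_all_cases`): strictly, a case without usable support
fails the gene (conservative; the default); relaxed, cases with no usable
call anywhere in the gene are skipped, which matters when genotyping depth
is marginal. The depth experiment in the test suite (Poisson mean depth 1,
50 paired simulations at reduced size — 4 genes, 12 background variants,
chosen to keep the suite fast) demonstrates the intended ordering: the
relaxed rule recovers the planted gene at least as often as the strict one.

A note on monotonicity: because control exclusion itself requires
depth-passing evidence, *raising* the depth threshold can in principle lift
an exclusion and re-admit a gene. The filter's candidate set is therefore
guaranteed monotone in the threshold only on the case-support side; the
property tests state exactly that (and full monotonicity when control depth
is uniformly high).

# Coding-consequence arithmetic

The consequence engine is deliberately self-contained: HGVS *c.* notation
in, protein arithmetic out.

* **Coordinates.** Genomic intervals are 0-based half-open internally; VCF
  and GFF3 convert at the boundary. CDS and protein positions are 1-based.
* **Normalisation.** VCF-style anchored indels are reduced to their minimal
  edit (shared prefix/suffix stripped), projected through the exon
  structure (alleles reverse-complemented and coordinates reflected for
  minus-strand transcripts), then 3′-shifted within the CDS to the most-3′
  equivalent position, as HGVS requires. An insertion whose sequence equals
  the immediately preceding CDS segment is renamed a duplication. The
  original genomic (left-anchored) representation is retained alongside, so
  records can still be matched against VCF keys — the two standards
  disagree and both interfaces are needed.
* **Stop scan.** The mutant CDS is translated from the original ATG with
  the standard genetic code only; the scan walks codon-by-codon and, when a
  frameshift reads through the reference stop, continues into the supplied
  3′UTR. The UTR is an explicit input (a transcript's annotated 3′UTR via
  `transcript_utr3()`), never an assumption; if the scan exhausts it, the
  record is typed `no_stop_found` rather than guessing.
* **First affected codon.** Reported as the codon of the first edited
  nucleotide (for insertions and duplications: the first *inserted*
  position, i.e. codon of `cds_end + 1`), even when that residue happens to
  be conserved — this matches how positional arithmetic is customarily
  quoted and keeps the number derivable from coordinates alone.
* **Dialect.** The hyphenated range form (`c.574-589del`) seen in print is
  accepted only between two plain positive integers and is never emitted;
  intron-offset notation (`c.88+2T>G`) is rejected as unsupported rather
  than misparsed.
* **Degenerate inputs.** Edits destroying the ATG short-circuit to
  `start_loss` with no downstream arithmetic. Variants outside the CDS are
  signalled as MODIFIER records, and variants straddling a CDS boundary
  (splice-region or stop-spanning) are signalled HIGH with no protein
  arithmetic — both are signals, not exceptions, so a batch annotation
  never aborts on an awkward variant.

The committed surrogate CDS fixture (636 nt: 633 coding + TAA; 211 residues
with the stop at codon 212) is synthetic. It is constructed so the two
published mutation classes exercise both scan regimes: the 16-bp deletion
at c.574–589 frameshifts at codon 192 and terminates only in the 3′UTR
scan, and the 2-bp duplication at c.20–21 frameshifts at codon 8 with a
premature stop at codon 15. It checks the arithmetic chain, not the real
transcript's sequence.

# Phase from allele-specific amplicons

The experimental readout being modelled is qualitative: an allele-specific
primer anchored on one site amplifies one chromosome, and Sanger traces
reveal the partner site's allele. The module generalises this to counted
observations so it is testable: per (anchor site, anchor allele) class the
majority observed allele votes *cis* when it matches the anchor category
(alt with alt, ref with ref) and *trans* otherwise. A class whose minority
fraction exceeds `noise_fraction` (default 5%, a parameter) makes the call
ambiguous, as do conflicting votes between classes. A call from a single
anchor class is still made but flagged low-confidence — *trans* should
ideally rest on both the mutant-anchored and reference-anchored amplicons.
The symmetry property (swapping which site is "A" and which "B", with
anchor/observed roles relabelled) holds exactly for noise-free observation
sets; with noise, relabelling moves minority reads into their own anchor
class, which is a different experiment.

# What the generator emulates — and what it does not

`simulate_reference()` builds one contig with multi-exon genes on both
strands (valid ATG…stop CDS, 2–4 exons, 150-nt 3′UTRs);
`simulate_cohort()` plants one causal gene with a 16-bp deletion and a 2-bp
duplication and assigns every case two mutant alleles (homozygous or
compound-heterozygous in trans, per `causal_config`). Defaults mirror the
study design this package abstracts:

| parameter | default | rationale |
|---|---|---|
| `n_cases` / `n_controls` | 2 / 6 | two affected genomes against six unaffected ones |
| `depth_mean` | 20 | deep case coverage (the sequenced cases were ~9× and ~40×); Poisson DP, floored at 0 |
| `carrier_rate_in_controls` | 0.04 | one expected carrier among ~27 unaffected animals |
| `missing_rate` | 0 | the published genotyping table is complete; missingness is a dial for the depth experiments |
| background allele frequencies | Beta(0.3, 8) | a rare-skewed site-frequency spectrum; most background variants are rare, a few common |
| `n_genes` / `n_background_variants` | 20 / 60 | desk-scale stand-in for the genome-wide funnel |

The master seed is split into named substreams (reference, variants,
genotypes, depth, missingness, amplicons), so changing one stage's
parameters does not scramble the draws of another; identical parameters and
seed give byte-identical output files.

Deliberate non-realism, and what passing tests therefore do and do not
show: there is no linkage disequilibrium, no relatedness between samples,
no sequencing-error model below the genotype level, and genotypes at
background variants are Hardy-Weinberg draws independent of phenotype. The
generator demonstrates that the filter's *logic* is correct and that the
discovery funnel behaves as designed; it cannot certify performance on real
genomes, where the variant density per gene is orders of magnitude higher
and a two-case filter retains many compound-heterozygous false candidates
that real studies narrow by impact annotation. That behaviour is visible in
miniature here: with two cases, background variants occasionally hand a
second gene to the candidate set, or let a control share enough background
heterozygotes with a case's implicated set to exclude the true gene —
which is the published filter behaving as specified, not a defect.

Compound-heterozygous causal pairs are always planted in trans (a recessive
model requires it); cis double-het decoys are a matter for the phase
module, whose amplicon simulation (200 reads per anchor class, 1% allele
dropout against the 5% calling threshold) keeps the planted configuration
recoverable.

# Tabulation and concordance

`genotype_table()` renders a cohort at two sites as the field's customary
`+/+`, `+/dup`, `dup/dup` strings grouped by phenotype (row order:
phenotype by first appearance, then genotype pair lexicographically — a
deterministic tie-break, not the print order of any particular
publication). `concordance_with_recessive_model()` partitions samples into
biallelic cases, wild-type controls, carrier controls and discordant
samples; a case with a missing genotype cannot demonstrate biallelism and
is counted discordant, the conservative choice.

The packaged genotyping fixture transcribes the published 35-animal table.
One transcription choice deserves a note: the source's prose and its table
disagree about the single carrier (prose: heterozygous for the duplication;
table: a royal pastel animal heterozygous for the *deletion*) and about the
affected-group genotypes; the fixture follows the table, and both readings
exist in the source. The fixture also packages uniform depth 30 for every
call, since the underlying genotyping is by Sanger sequencing where the
depth filter has no analogue.

# Test-suite scale choices

Problem sizes in the suite are the package's own: exhaustive
filter-vs-oracle enumeration runs at 3 samples × 2 variants over all 4⁶
genotype-class matrices (two role splits, one- and two-gene layouts) plus a
1-case/1-control depth enumeration, with random equivalence trials at the
full 5 × 8 × 2 size — enumerating all genotype matrices at 5 × 8 (4⁴⁰
states) is not computable anywhere, so the enumeration covers the rule's
decision surface at the smallest size where every clause can fire.
Consequence-engine equivalence against an independent Biostrings-based
translator runs 500 random CDS × edit trials; round-trip identities run on
100 random cohorts and 200 random HGVS expressions; recovery and phase
properties run across 20 and 50 fixed seeds respectively.

# Known limitations

* Intron-offset HGVS and non-standard genetic codes are unsupported.
* A deletion spanning the CDS/3′UTR boundary within the final exon is
  signalled like a splice-region variant (HIGH, no arithmetic) rather than
  being resolved as a stop-spanning delins.
* The filter has no statistical component: no kinship correction, no
  association testing, no multiple-phenotype modelling. It is a sieve, and
  its output is a candidate set, not an inference.
* Gene membership is by transcript span, so two overlapping genes both
  claim a shared variant; candidates must be deduplicated downstream by
  annotation.
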