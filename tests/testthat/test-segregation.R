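# The recessive case/control discovery filter.

test_that("genotype classification is exhaustive and rejects bad indices", {
  expect_equal(genotype_class(1L, 1L), "hom_alt")
  expect_equal(genotype_class(0L, 1L), "het")
  expect_equal(genotype_class(1L, 0L), "het")
  expect_equal(genotype_class(0L, 0L), "hom_ref")
  expect_equal(genotype_class(NA, NA), "missing")
  expect_equal(genotype_class(NA, 1L), "missing")
  expect_error(genotype_class(2L, 0L), "biallelic")
})

test_that("depth filter reads 'greater than 2' strictly", {
  p <- filter_params()
  expect_true(passes_depth(3L, p))
  expect_false(passes_depth(2L, p))
  expect_false(passes_depth(NA_integer_, p))
  expect_equal(passes_depth(c(1, 3, NA, 40), p), c(FALSE, TRUE, FALSE, TRUE))
  expect_error(filter_params(-1), "min_depth_exclusive")
})

make_two_site_cohort <- function(gt, dp = NULL, roles) {
  # gt: list per sample of c(a1, b1, a2, b2); two variants inside gene G
  ns <- length(gt)
  vt <- variant_table(rep("c1", 2), c(120L, 180L), c("A", "C"), c("T", "G"),
                      id = c("v_del", "v_dup"))
  sm <- sample_sheet(sprintf("s%d", seq_len(ns)), role = roles)
  aa <- vapply(gt, function(g) g[c(1, 3)], integer(2))
  ab <- vapply(gt, function(g) g[c(2, 4)], integer(2))
  if (is.null(dp)) dp <- matrix(30L, 2, ns)
  cohort_genotypes(vt, sm, aa, ab, dp)
}

geneG <- list(span_gene("G", "c1", 100, 300))

test_that("compound-het groups need two depth-passing hets in one gene", {
  co <- make_two_site_cohort(list(c(0L, 1L, 1L, 0L), c(0L, 0L, 0L, 1L)),
                             roles = c("case", "control"))
  g <- compound_het_groups(co, "s1", geneG)
  expect_named(g, "G")
  expect_setequal(g$G$id, c("v_del", "v_dup"))
  expect_length(compound_het_groups(co, "s2", geneG), 0L)  # one het only
  # depth: het at DP 5 and DP 2 -> the DP-2 call fails DP > 2, group dies
  co2 <- make_two_site_cohort(list(c(0L, 1L, 0L, 1L)),
                              dp = matrix(c(5L, 2L), 2, 1),
                              roles = "case")
  expect_length(compound_het_groups(co2, "s1", geneG), 0L)
  expect_error(compound_het_groups(co, "nope", geneG), "unknown sample")
})

test_that("homozygous cases against wild-type controls nominate the gene", {
  co <- make_two_site_cohort(
    list(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L),
         c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L)),
    roles = c("case", "case", "control", "control"))
  cs <- recessive_candidates(co, geneG)
  expect_length(cs$entries, 1L)
  expect_equal(cs$entries[[1]]$gene_id, "G")
  expect_equal(cs$entries[[1]]$mode, "homozygous")
  expect_equal(cs$entries[[1]]$variants$id, "v_del")
})

test_that("hom and double-het cases mix; het carriers never exclude", {
  co <- make_two_site_cohort(
    list(c(1L, 1L, 0L, 0L),            # case1 hom at v_del
         c(0L, 1L, 1L, 0L),            # case2 het at both (compound het)
         c(0L, 0L, 0L, 0L),            # control wild type
         c(0L, 1L, 0L, 0L)),           # control single-het carrier
    roles = c("case", "case", "control", "control"))
  cs <- recessive_candidates(co, geneG)
  expect_length(cs$entries, 1L)
  e <- cs$entries[[1]]
  expect_setequal(e$variants$id, c("v_del", "v_dup"))
  expect_equal(e$per_case$s1$mode, "homozygous")
  expect_equal(e$per_case$s2$mode, "compound_het")
  # one control homozygous at v_del excludes the gene entirely
  co2 <- make_two_site_cohort(
    list(c(1L, 1L, 0L, 0L), c(0L, 1L, 1L, 0L),
         c(1L, 1L, 0L, 0L), c(0L, 1L, 0L, 0L)),
    roles = c("case", "case", "control", "control"))
  expect_length(recessive_candidates(co2, geneG)$entries, 0L)
})

test_that("cohorts without cases or controls are a configuration error", {
  co <- make_two_site_cohort(list(c(1L, 1L, 0L, 0L)), roles = "case")
  expect_error(recessive_candidates(co, geneG), "configuration error")
  expect_error(recessive_site_filter(co), "configuration error")
})

test_that("missing case genotypes obey the strict/relaxed switch", {
  co <- make_two_site_cohort(
    list(c(1L, 1L, 0L, 0L), c(NA, NA, NA, NA), c(0L, 0L, 0L, 0L)),
    roles = c("case", "case", "control"))
  strict <- recessive_candidates(co, geneG, filter_params())
  expect_length(strict$entries, 0L)
  relaxed <- recessive_candidates(
    co, geneG, filter_params(require_called_in_all_cases = FALSE))
  expect_length(relaxed$entries, 1L)
})

test_that("filter equals the brute-force oracle on random cohorts", {
  n_match <- 0
  for (s in 1:200) {
    roles <- c("case", sample(c("case", "control"), 4, TRUE), "control")
    co <- random_cohort(nv = 8, ns = 6, seed = 1000 + s, roles = roles)
    tx <- list(span_gene("gA", "c1", 0, 2500),
               span_gene("gB", "c1", 2500, 5100))
    got <- sort(vapply(recessive_candidates(co, tx)$entries, `[[`, "",
                       "gene_id"))
    want <- oracle_recessive(co, spans_of(tx))
    expect_equal(got, want)
    n_match <- n_match + identical(got, want)
  }
  expect_equal(n_match, 200)
})

test_that("raising the depth threshold only removes case support", {
  # control evidence kept at uniformly high depth so exclusions cannot be
  # lifted; under that regime the candidate set shrinks monotonically
  for (s in 1:40) {
    co <- random_cohort(nv = 8, ns = 6, seed = 3000 + s,
                        roles = rep(c("case", "control"), 3))
    co$depth[, co$samples$role == "control"] <- 50L
    tx <- list(span_gene("gA", "c1", 0, 2500),
               span_gene("gB", "c1", 2500, 5100))
    prev <- NULL
    for (thr in c(0, 2, 7, 29)) {
      cur <- vapply(recessive_candidates(co, tx, filter_params(thr))$entries,
                    `[[`, "", "gene_id")
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("adding a case or a control never adds a gene", {
  for (s in 1:40) {
    co <- random_cohort(nv = 8, ns = 5, seed = 5000 + s,
                        roles = c("case", "case", "control", "control",
                                  "unassigned"))
    tx <- list(span_gene("gA", "c1", 0, 2500),
               span_gene("gB", "c1", 2500, 5100))
    base <- vapply(recessive_candidates(co, tx)$entries, `[[`, "", "gene_id")
    for (new_role in c("case", "control")) {
      co2 <- co
      co2$samples$role[5] <- new_role
      grown <- vapply(recessive_candidates(co2, tx)$entries, `[[`, "",
                      "gene_id")
      expect_true(all(grown %in% base))
    }
  }
})

test_that("the genotyping-table fixture nominates only the surrogate gene", {
  t1 <- table1_fixture()
  cs <- recessive_candidates(t1$cohort, t1$transcripts)
  expect_length(cs$entries, 1L)
  expect_equal(cs$entries[[1]]$gene_id, "RAB38S")
  expect_setequal(cs$entries[[1]]$variants$id, c("causal_del", "causal_dup"))
  # the single royal pastel +/del carrier is neither homozygous nor
  # compound heterozygous, so it must not have excluded the gene
  carrier <- which(t1$samples$phenotype == "Royal pastel" &
                   genotype_class(t1$cohort$allele_a[
                     t1$cohort$variants$id == "causal_del", ],
                     t1$cohort$allele_b[
                       t1$cohort$variants$id == "causal_del", ]) == "het")
  expect_length(carrier, 1L)
})

test_that("per-variant homozygous-only mode applies the site-wise rule", {
  co <- make_two_site_cohort(
    list(c(1L, 1L, 0L, 0L), c(1L, 1L, 1L, 1L),
         c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 0L)),
    roles = c("case", "case", "control", "control"))
  sel <- recessive_site_filter(co)
  expect_equal(sel$id, "v_del")  # v_dup is hom in a control
})

test_that("candidate tables carry per-sample genotype classes", {
  t1 <- table1_fixture()
  cs <- recessive_candidates(t1$cohort, t1$transcripts)
  tab <- candidates_table(cs, t1$cohort)
  expect_equal(nrow(tab), 2L)
  expect_true(all(t1$samples$sample_id %in% names(tab)))
  expect_equal(tab$gene_id, rep("RAB38S", 2))
})
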