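# HGVS c. notation and the coding-consequence engine.

test_that("published-dialect HGVS parses and normalises", {
  v <- parse_hgvs_c("RAB38:c.574-589del")
  expect_equal(v$kind, "deletion")
  expect_equal(c(v$cds_start, v$cds_end), c(574L, 589L))
  expect_equal(v$deleted_len, 16L)
  d <- parse_hgvs_c("c.20_21dup")
  expect_equal(d$kind, "duplication")
  expect_equal(c(d$cds_start, d$cds_end), c(20L, 21L))
  expect_equal(coding_net_change(d), 2L)
  s <- parse_hgvs_c("c.5A>T")
  expect_equal(s$kind, "substitution")
  expect_equal(s$cds_start, 5L)
  expect_equal(s$ref_seq, "A"); expect_equal(s$inserted_seq, "T")
  # "-" and "_" parse identically
  expect_equal(parse_hgvs_c("c.574-589del"), parse_hgvs_c("c.574_589del"))
})

test_that("unsupported dialects and length mismatches are rejected", {
  expect_error(parse_hgvs_c("c.88+2T>G"), "dialect")
  expect_error(parse_hgvs_c("c.88-2del"), "dialect|inverted")
  expect_error(parse_hgvs_c("c.20_21dupCTT"), "does not match range")
  expect_error(parse_hgvs_c("c.20_22ins"), "cannot parse|without sequence")
  expect_error(parse_hgvs_c("c.20_22insAT"), "adjacent")
  expect_error(parse_hgvs_c("g.100del"), "not c\\.")
})

test_that("formatting emits the standard separator and round-trips", {
  expect_equal(format_hgvs_c(parse_hgvs_c("c.574-589del")), "c.574_589del")
  expect_equal(format_hgvs_c(parse_hgvs_c("c.20-21dup")), "c.20_21dup")
  expect_equal(format_hgvs_c(coding_variant("substitution", 5,
                                            ref_seq = "A",
                                            inserted_seq = "T")), "c.5A>T")
  # parse/format round trip on random coding variants
  set.seed(99)
  for (i in 1:200) {
    rv <- random_coding_variant(300)
    v <- if (rv$kind == "substitution") {
      coding_variant("substitution", rv$s, ref_seq = "A",
                     inserted_seq = sample(c("C", "G", "T"), 1))
    } else if (rv$kind %in% c("deletion", "duplication")) {
      coding_variant(rv$kind, rv$s, rv$e)
    } else coding_variant(rv$kind, rv$s, rv$e, inserted_seq = rv$ins)
    expect_equal(parse_hgvs_c(format_hgvs_c(v)), v)
  }
})

test_that("first affected codon matches the published positions", {
  expect_equal(first_affected_codon(parse_hgvs_c("c.574_589del")), 192L)
  expect_equal(first_affected_codon(parse_hgvs_c("c.20_21dup")), 8L)
  expect_equal(first_affected_codon(parse_hgvs_c("c.1A>T")), 1L)
  expect_equal(first_affected_codon(parse_hgvs_c("c.3_4insAA")), 2L)
})

test_that("surrogate CDS frameshifts reproduce the published arithmetic", {
  fx <- rab38_surrogate_fixture()
  expect_equal(nchar(fx$cds), 636L)
  expect_equal(nchar(translate_cds(fx$cds, to_stop = TRUE)), 211L)
  del <- predict_consequence(parse_hgvs_c("c.574_589del"), fx$cds, fx$utr3)
  expect_equal(del$type, "frameshift")
  expect_true(del$is_frameshift)
  expect_equal(del$first_affected_codon, 192L)
  expect_equal(del$wt_stop_codon_index, 212L)
  expect_equal(del$wt_protein_len, 211L)
  expect_gt(del$mut_stop_codon_index, 212L)  # stop found in the 3'UTR scan
  dup <- predict_consequence(parse_hgvs_c("c.20_21dup"), fx$cds, fx$utr3)
  expect_equal(dup$type, "frameshift")
  expect_equal(dup$first_affected_codon, 8L)
  expect_lt(dup$mut_stop_codon_index, 50L)   # premature stop
  expect_equal(dup$impact, "HIGH")
})

test_that("toy substitutions classify as expected", {
  cds <- "ATGAAATAA"
  sg <- predict_consequence(parse_hgvs_c("c.4A>T"), cds)
  expect_equal(sg$type, "stop_gain")
  expect_equal(sg$mut_protein_len, 1L)
  syn <- predict_consequence(parse_hgvs_c("c.6A>G"), cds)  # AAA -> AAG (Lys)
  expect_equal(syn$type, "synonymous")
  mis <- predict_consequence(parse_hgvs_c("c.4A>C"), cds)
  expect_equal(mis$type, "missense")
  sl <- predict_consequence(parse_hgvs_c("c.7T>C"), cds, "TTTTAATT")
  expect_equal(sl$type, "stop_loss")
  startl <- predict_consequence(parse_hgvs_c("c.2T>C"), cds)
  expect_equal(startl$type, "start_loss")
  expect_equal(startl$impact, "HIGH")
  inf <- predict_consequence(parse_hgvs_c("c.4_6del"), cds)
  expect_equal(inf$type, "inframe_indel")
  expect_equal(inf$impact, "MODERATE")
})

test_that("impact tiers follow the fixed ontology", {
  expect_equal(classify_impact("frameshift"), "HIGH")
  expect_equal(classify_impact("stop_gain"), "HIGH")
  expect_equal(classify_impact("splice_region"), "HIGH")
  expect_equal(classify_impact("no_stop_found"), "HIGH")
  expect_equal(classify_impact("missense"), "MODERATE")
  expect_equal(classify_impact("inframe_indel"), "MODERATE")
  expect_equal(classify_impact("synonymous"), "LOW")
  expect_equal(classify_impact("non_coding"), "MODIFIER")
})

test_that("frameshift flag tracks net length change mod 3 for all kinds", {
  set.seed(42)
  for (i in 1:100) {
    cds <- random_cds_string(40)
    rv <- random_coding_variant(nchar(cds) - 3)
    v <- if (rv$kind == "substitution") {
      refb <- substr(cds, rv$s, rv$s)
      coding_variant("substitution", rv$s, ref_seq = refb,
                     inserted_seq = sample(setdiff(c("A", "C", "G", "T"),
                                                   refb), 1))
    } else if (rv$kind %in% c("deletion", "duplication")) {
      coding_variant(rv$kind, rv$s, rv$e)
    } else coding_variant(rv$kind, rv$s, rv$e, inserted_seq = rv$ins)
    rec <- predict_consequence(v, cds, "ACGTACGTACGTTAAACGT")
    expect_equal(rec$is_frameshift, coding_net_change(v) %% 3L != 0L)
    if (rec$type == "frameshift") expect_true(rec$is_frameshift)
  }
})

test_that("engine matches the independent translation oracle", {
  set.seed(7)
  n_ok <- 0
  for (i in 1:500) {
    cds <- random_cds_string(sample(20:100, 1))
    utr3 <- paste(sample(c("A", "C", "G", "T"), sample(30:90, 1), TRUE),
                  collapse = "")
    rv <- random_coding_variant(nchar(cds) - 3)
    v <- if (rv$kind == "substitution") {
      refb <- substr(cds, rv$s, rv$s)
      coding_variant("substitution", rv$s, ref_seq = refb,
                     inserted_seq = sample(setdiff(c("A", "C", "G", "T"),
                                                   refb), 1))
    } else if (rv$kind %in% c("deletion", "duplication")) {
      coding_variant(rv$kind, rv$s, rv$e)
    } else coding_variant(rv$kind, rv$s, rv$e, inserted_seq = rv$ins)
    rec <- predict_consequence(v, cds, utr3)
    ora <- oracle_consequence(v, cds, utr3)
    expect_equal(rec$wt_stop_codon_index, ora$wt_stop)
    if (rec$type == "start_loss") {
      expect_false(startsWith(ora$mutant, "ATG"))
    } else {
      expect_equal(rec$mut_stop_codon_index, ora$mut_stop)
      if (!is.na(ora$mut_stop))
        expect_equal(rec$mut_protein_len, ora$mut_stop - 1L)
      expect_equal(rec$is_frameshift, ora$net %% 3L != 0L)
    }
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 500)
})

test_that("anchored genomic indels project onto the CDS", {
  # 100-nt contig; single-exon CDS at genomic 101..? -> use a padded layout
  set.seed(5)
  lead <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  cds <- random_cds_string(30)  # 90 nt
  seq <- paste0(lead, cds, "TTTTTTTTTT")
  ref <- reference_sequences(setNames(list(seq), "chrP"))
  t <- transcript_model("gP", "gP.t1", "chrP", "+",
                        data.frame(start = 100, end = 200),
                        data.frame(start = 100, end = 190))
  # VCF del "pos=110 ref=<110..112> alt=<110>" removes CDS bases 11-12
  r3 <- substr(seq, 110, 112)
  pr <- project_to_cds(list(chrom = "chrP", pos = 110L, ref = r3,
                            alt = substr(r3, 1, 1)), t, ref)
  expect_equal(pr$status, "coding")
  cv <- pr$coding_variant
  expect_equal(cv$kind, "deletion")
  # 3'-shifting may move the range but the edit must be equivalent
  expect_equal(apply_coding_edit(cv, cds),
               paste0(substr(cds, 1, 10), substr(cds, 13, 90)))
  expect_equal(cv$deleted_len, 2L)
})

test_that("minus-strand projection mirrors the plus-strand consequence", {
  set.seed(6)
  for (i in 1:20) {
    lead <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
    cds <- random_cds_string(20)  # 60 nt
    tail <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    seq <- paste0(lead, cds, tail)
    ref <- reference_sequences(setNames(list(seq), "chrM"))
    t <- transcript_model("gM", "gM.t1", "chrM", "+",
                          data.frame(start = 50, end = 140),
                          data.frame(start = 50, end = 110))
    # random anchored deletion fully inside the CDS
    p <- sample(55:100, 1); w <- sample(1:4, 1)
    v <- data.frame(chrom = "chrM", pos = p,
                    ref = substr(seq, p, p + w), alt = substr(seq, p, p),
                    id = "x", stringsAsFactors = FALSE)
    mir <- mirror_minus(ref, t)
    vm <- mirror_variant(v, nchar(seq))
    pr_plus <- project_to_cds(v, t, ref)
    pr_minus <- project_to_cds(vm, mir$t, mir$ref)
    expect_equal(pr_minus$status, pr_plus$status)
    if (pr_plus$status == "coding") {
      expect_equal(pr_minus$coding_variant, pr_plus$coding_variant)
      rec_p <- predict_consequence(pr_plus$coding_variant, cds,
                                   transcript_utr3(t, ref))
      rec_m <- predict_consequence(pr_minus$coding_variant,
                                   spliced_cds(mir$t, mir$ref),
                                   transcript_utr3(mir$t, mir$ref))
      expect_equal(rec_m, rec_p)
    }
  }
})

test_that("insertions become duplications only when they copy the
           preceding CDS segment", {
  cds <- "ATGCATCGGAAATAA"
  seq <- paste0("GGGGGGGGGG", cds, "CCCCCCCCCC")
  ref <- reference_sequences(setNames(list(seq), "chrD"))
  t <- transcript_model("gD", "gD.t1", "chrD", "+",
                        data.frame(start = 10, end = 35),
                        data.frame(start = 10, end = 25))
  # insert a copy of CDS bases 4..6 ("CAT") right after position 6
  pr <- project_to_cds(list(chrom = "chrD", pos = 16L, ref = "T",
                            alt = "TCAT"), t, ref)
  expect_equal(pr$coding_variant$kind, "duplication")
  # 3'-shifting renders "CAT after 6" as its most-3' equivalent, dup 5..7
  expect_equal(c(pr$coding_variant$cds_start, pr$coding_variant$cds_end),
               c(5L, 7L))
  expect_equal(apply_coding_edit(pr$coding_variant, "ATGCATCGGAAATAA"),
               paste0("ATGCAT", "CAT", "CGGAAATAA"))
  # a non-copy insertion stays an insertion
  pr2 <- project_to_cds(list(chrom = "chrD", pos = 16L, ref = "T",
                             alt = "TGGA"), t, ref)
  expect_equal(pr2$coding_variant$kind, "insertion")
})

test_that("variants outside or straddling the CDS signal instead of erroring", {
  toy <- toy_plus()
  # intronless toy: upstream variant is non-coding
  pr <- project_to_cds(list(chrom = "chrT", pos = 3L, ref = "G", alt = "A"),
                       toy$t, toy$ref)
  expect_equal(pr$status, "non_coding")
  expect_equal(pr$impact, "MODIFIER")
  # deletion spanning the CDS 3' boundary is a splice-region signal
  pr2 <- project_to_cds(list(chrom = "chrT", pos = 18L,
                             ref = substr(unclass(toy$ref)[[1]], 18, 21),
                             alt = substr(unclass(toy$ref)[[1]], 18, 18)),
                        toy$t, toy$ref)
  expect_equal(pr2$status, "splice_region")
  expect_equal(pr2$impact, "HIGH")
})

test_that("protein enlargement follows the stop indices", {
  fx <- rab38_surrogate_fixture()
  del <- predict_consequence(parse_hgvs_c("c.574_589del"), fx$cds, fx$utr3)
  expect_equal(percent_enlargement(del),
               100 * (del$mut_protein_len - 211) / 211)
  expect_gte(percent_enlargement(del), 30)
})
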