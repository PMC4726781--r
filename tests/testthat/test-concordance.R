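gt_tbl <- function(class) {
  p <- gt_of_class(class)
  tibble::tibble(gt_a1 = p[1], gt_a2 = p[2])
}

test_that("compare_genotypes matches the exhaustive 3x3 truth table", {
  for (i in seq_len(nrow(oracle_compare_table))) {
    row <- oracle_compare_table[i, ]
    got <- compare_genotypes(gt_tbl(row$test), gt_tbl(row$truth))
    expect_equal(got, row$class, info = paste(row$test, "vs", row$truth))
  }
})

test_that("swapping platforms exchanges false positives and false negatives", {
  classes <- c("hom_ref", "het", "hom_alt")
  flip <- c(FALSE_POSITIVE = "FALSE_NEGATIVE",
            FALSE_NEGATIVE = "FALSE_POSITIVE",
            CONCORDANT = "CONCORDANT",
            MIXED_DISCORDANT = "MIXED_DISCORDANT")
  for (a in classes) for (b in classes) {
    fwd <- compare_genotypes(gt_tbl(a), gt_tbl(b))
    rev <- compare_genotypes(gt_tbl(b), gt_tbl(a))
    expect_equal(rev, unname(flip[fwd]), info = paste(a, b))
  }
})

test_that("genotype order is ignored (multiset comparison)", {
  t1 <- tibble::tibble(gt_a1 = "alt", gt_a2 = "ref")
  t2 <- tibble::tibble(gt_a1 = "ref", gt_a2 = "alt")
  expect_equal(compare_genotypes(t1, t2), "CONCORDANT")
})

test_that("foreign-allele involvement is mixed-discordant", {
  other_het <- tibble::tibble(gt_a1 = "ref", gt_a2 = "other")
  expect_equal(compare_genotypes(other_het, gt_tbl("het")), "MIXED_DISCORDANT")
  expect_equal(compare_genotypes(gt_tbl("hom_ref"), other_het),
               "MIXED_DISCORDANT")
})

test_that("compare_genotypes refuses misaligned sites and no-calls", {
  a <- dplyr::as_tibble(mk_pair("het", "het")$test)
  b <- dplyr::mutate(a, position = position + 1L)
  expect_error(compare_genotypes(a, b), "site keys differ")
  nc <- tibble::tibble(gt_a1 = NA_character_, gt_a2 = NA_character_)
  expect_error(compare_genotypes(nc, gt_tbl("het")), "no-call")
})

test_that("the classification cascade applies rules in order", {
  th <- filter_thresholds()
  # low-depth test call is not evaluable regardless of truth
  p <- mk_pair("het", "het", test_depth = 3L)
  expect_equal(classify_calls(p$test, p$truth, th)$classification,
               "NOT_EVALUABLE")
  # unconfident truth routes to missing-truth
  p <- mk_pair("het", "het", truth_depth = 8L)
  cl <- classify_calls(p$test, p$truth, th)
  expect_equal(cl$classification, "MISSING_TRUTH")
  expect_equal(cl$missing_reason, "low_truth_depth")
  # evaluable vs confident het is concordant
  p <- mk_pair("het", "het")
  expect_equal(classify_calls(p$test, p$truth, th)$classification,
               "CONCORDANT")
  # tranche exclusion precedes evaluability (stratification first)
  p <- mk_pair("het", "het", test_depth = 3L, tranche = "TRANCHE_99_999")
  expect_equal(classify_calls(p$test, p$truth, th)$classification,
               "EXCLUDED_TRANCHE")
  # a platform-emitted no-call is a no-call, not a low-quality call
  p <- mk_pair("none", "het")
  expect_equal(classify_calls(p$test, p$truth, th)$classification, "NO_CALL")
  # absent truth row is missing truth
  p <- mk_pair("het", "het")
  truth_other <- mk_calls(tibble::tibble(
    sample = "S2", contig = "t1", position = 110L, ref = "A", alt = "G",
    rsid = "rs001", gt = "het", depth = 100L
  ), "TRUTH_AMPLICON")
  cl <- classify_calls(p$test, truth_other, filter_thresholds())
  expect_equal(cl$classification, "MISSING_TRUTH")
  expect_equal(cl$missing_reason, "truth_absent")
})

test_that("panel comparisons gate the truth side on call rate", {
  s <- mk_sites(1)
  test <- mk_calls(tibble::tibble(
    sample = "S1", contig = s$contig, position = s$position, ref = s$ref,
    alt = s$alt, gt = "het", depth = 50L, gq = 99, tranche = "PASS_99"
  ), "TEST_WES")
  panel_low <- mk_calls(tibble::tibble(
    sample = "S1", contig = s$contig, position = s$position, ref = s$ref,
    alt = s$alt, gt = "het", call_rate = 84
  ), "PANEL")
  cl <- classify_calls(test, panel_low, filter_thresholds())
  expect_equal(cl$classification, "MISSING_TRUTH")
  expect_equal(cl$missing_reason, "low_call_rate")
  panel_ok <- mk_calls(tibble::tibble(
    sample = "S1", contig = s$contig, position = s$position, ref = s$ref,
    alt = s$alt, gt = "het", call_rate = 95
  ), "PANEL")
  expect_equal(classify_calls(test, panel_ok, filter_thresholds())$classification,
               "CONCORDANT")
})

test_that("summary counts satisfy the partition identities on random fixtures", {
  set.seed(21)
  for (i in 1:25) {
    cls <- random_classified()
    s <- summarize_concordance(cls)
    expect_equal(s$n_total_calls,
                 s$n_low_quality + s$n_no_calls + s$n_missing_truth +
                   s$n_evaluated)
    expect_equal(s$n_evaluated, s$n_concordant + s$n_discordant)
    expect_equal(s$n_discordant,
                 s$n_false_positive + s$n_false_negative + s$n_mixed)
    expect_equal(s$n_total_calls + s$n_excluded_tranche, nrow(cls))
    # 100% concordance iff zero discordant calls
    if (s$n_evaluated > 0) {
      expect_equal(s$concordance_rate == 100, s$n_discordant == 0)
    } else {
      expect_true(is.na(s$concordance_rate))
    }
  }
})

test_that("summarize reproduces the worked-example concordance rates", {
  mk <- function(n_eval, n_disc) {
    tibble::tibble(classification = rep(c("CONCORDANT", "FALSE_NEGATIVE"),
                                        c(n_eval - n_disc, n_disc)))
  }
  expect_equal(format_rate(summarize_concordance(mk(741, 3))$concordance_rate),
               "99.60")
  expect_equal(format_rate(summarize_concordance(mk(1249, 136))$concordance_rate),
               "89.11")
  expect_equal(format_rate(summarize_concordance(mk(719, 8))$concordance_rate),
               "98.89")
  expect_equal(format_rate(summarize_concordance(mk(500, 0))$concordance_rate),
               "100.00")
})

test_that("stratified report nests the strict stratum inside the relaxed one", {
  sim_cfg <- simulation_config(n_samples = 12, n_sites = 20, seed = 33)
  truth <- generate_truth(sim_cfg)
  test <- simulate_test_callset(truth, sim_cfg)
  rep <- build_stratified_report(test, truth)
  expect_lte(rep$strict$n_discordant, rep$relaxed$n_discordant)
  expect_lte(rep$strict$n_total_calls, rep$relaxed$n_total_calls)
  # calls at strict-cut sites classify identically under both cuts
  pass_calls <- dplyr::filter(rep$calls, tranche == "PASS_99")
  expect_equal(pass_calls$class_strict, pass_calls$class_relaxed)
  # relaxed counts decompose as strict + tranche-only (brute-force recount)
  tranche_calls <- dplyr::filter(rep$calls, tranche == "TRANCHE_99_999")
  expect_equal(rep$relaxed$n_evaluated,
               rep$strict$n_evaluated +
                 sum(tranche_calls$class_relaxed %in%
                       c("CONCORDANT", "FALSE_POSITIVE", "FALSE_NEGATIVE",
                         "MIXED_DISCORDANT")))
  expect_equal(rep$relaxed$n_discordant,
               rep$strict$n_discordant +
                 sum(tranche_calls$class_relaxed %in%
                       c("FALSE_POSITIVE", "FALSE_NEGATIVE",
                         "MIXED_DISCORDANT")))
})

test_that("tidy and glance expose the report tables", {
  fx <- example_bookkeeping_callsets()
  rep <- build_stratified_report(fx$test, fx$truth)
  g <- glance(rep)
  expect_equal(g$stratum, c("strict", "relaxed"))
  expect_equal(g$n_evaluated, c(741L, 1249L))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(sum(tidy(rep)$in_strict_cut), 27)
})
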