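test_that("config validation lists offending fields", {
  expect_error(simulation_config(base_error = 2), "base_error")
  expect_error(simulation_config(n_samples = 0), "n_samples")
  expect_error(simulation_config(tranche_fractions = c(PASS_99 = 0.5,
                                                       TRANCHE_99_999 = 0.2,
                                                       ABOVE_999 = 0)),
               "tranche_fractions")
})

test_that("degenerate allele frequencies give fixed genotypes", {
  cfg0 <- simulation_config(n_samples = 20, n_sites = 3, allele_freqs = 0,
                            missing_truth_rate = 0, seed = 1)
  truth0 <- generate_truth(cfg0)
  expect_true(all(truth0$gt_a1 == "ref" & truth0$gt_a2 == "ref"))
  cfg1 <- simulation_config(n_samples = 20, n_sites = 3, allele_freqs = 1,
                            missing_truth_rate = 0, seed = 1)
  truth1 <- generate_truth(cfg1)
  expect_true(all(truth1$gt_a1 == "alt" & truth1$gt_a2 == "alt"))
})

test_that("the het fraction at q = 0.5 sits within 3 standard errors of 1/2", {
  cfg <- simulation_config(n_samples = 10000, n_sites = 1, allele_freqs = 0.5,
                           missing_truth_rate = 0, seed = 23)
  truth <- generate_truth(cfg)
  het <- mean(truth$gt_a1 != truth$gt_a2)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("generated truth conforms to Hardy-Weinberg proportions", {
  for (seed in c(101, 202)) {
    cfg <- simulation_config(n_samples = 2000, n_sites = 4,
                             allele_freqs = c(0.1, 0.2, 0.35, 0.5),
                             missing_truth_rate = 0, seed = seed)
    truth <- dplyr::as_tibble(generate_truth(cfg))
    for (rs in unique(truth$rsid)) {
      g <- dplyr::filter(truth, rsid == rs)
      dosage <- (g$gt_a1 == "alt") + (g$gt_a2 == "alt")
      q <- mean(dosage) / 2
      expected <- 2000 * c((1 - q)^2, 2 * q * (1 - q), q^2)
      observed <- tabulate(dosage + 1, 3)
      p <- stats::chisq.test(observed, p = expected / sum(expected))$p.value
      expect_gt(p, 0.001)
    }
  }
})

test_that("identical seed and config reproduce byte-identical outputs", {
  cfg <- simulation_config(n_samples = 6, n_sites = 10, seed = 77,
                           panel_site_fraction = 0.8, n_panel_only_sites = 2)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  run_simulate(cfg, out_dir = d1)
  run_simulate(cfg, out_dir = d2)
  for (f in c("test.vcf", "truth.vcf", "panel.tsv", "targets.bed",
              "injected_errors.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("genotype calls from read counts match the likelihood oracle", {
  expect_equal(genotype_quality(18L, 0L)$call, "hom_ref")
  res <- genotype_quality(0L, 30L)
  expect_equal(res$call, "hom_alt")
  expect_equal(res$gq, oracle_genotype_quality(0, 30)$gq)
  # overwhelming evidence saturates at the Phred-99 cap
  expect_equal(genotype_quality(0L, 40L)$gq, 99)
  het <- genotype_quality(10L, 10L)
  want <- oracle_genotype_quality(10, 10)
  expect_equal(het$call, "het")
  expect_equal(het$gq, want$gq)
  # no reads, no call
  none <- genotype_quality(0L, 0L)
  expect_true(is.na(none$call) && is.na(none$gq))
})

test_that("genotype_quality matches exhaustive enumeration up to depth 12", {
  for (d in 1:12) {
    for (a in 0:d) {
      got <- genotype_quality(d - a, a)
      want <- oracle_genotype_quality(d - a, a)
      expect_equal(got$call, want$call, info = paste(d - a, a))
      expect_equal(got$gq, want$gq, info = paste(d - a, a))
    }
  }
})

test_that("the injected-error ledger equals the pipeline's discordant calls", {
  cfg <- simulation_config(
    n_samples = 25, n_sites = 40, mean_depth = 80, depth_dispersion = 50,
    missing_truth_rate = 0, error_rate_pass = 0.05, error_rate_tranche = 0.3,
    seed = 55
  )
  truth <- generate_truth(cfg)
  test <- simulate_test_callset(truth, cfg)
  cl <- classify_calls(test, truth, filter_thresholds(tranche_cut = "relaxed"))
  discordant <- dplyr::filter(
    cl, classification %in% c("FALSE_POSITIVE", "FALSE_NEGATIVE",
                              "MIXED_DISCORDANT"))
  ledger <- attr(test, "injected_errors")
  expect_equal(nrow(discordant), nrow(ledger))
  expect_setequal(paste(discordant$sample, discordant$rsid),
                  paste(ledger$sample, ledger$rsid))
})

test_that("tranche-heavy error reproduces a strict-vs-relaxed concordance gap", {
  gaps <- vapply(c(91, 92, 93), function(seed) {
    cfg <- simulation_config(n_samples = 20, n_sites = 40, mean_depth = 80,
                             depth_dispersion = 50, missing_truth_rate = 0,
                             error_rate_pass = 0.005,
                             error_rate_tranche = 0.3, seed = seed)
    truth <- generate_truth(cfg)
    test <- simulate_test_callset(truth, cfg)
    rep <- build_stratified_report(test, truth)
    rep$strict$concordance_rate - rep$relaxed$concordance_rate
  }, 0)
  expect_true(all(gaps > 0))
})

test_that("panel corruption stays within 3 binomial SD of its rate", {
  for (seed in c(301, 302, 303)) {
    cfg <- simulation_config(n_samples = 40, n_sites = 40,
                             missing_truth_rate = 0,
                             panel_error_rate = 0.05, seed = seed)
    truth <- generate_truth(cfg)
    panel <- simulate_panel_callset(truth, cfg)
    n <- nrow(panel)
    k <- nrow(attr(panel, "injected_errors"))
    expect_lt(abs(k - n * 0.05), 3 * sqrt(n * 0.05 * 0.95) + 1)
  }
})

test_that("panel-only sites and panel subsets exercise site matching", {
  cfg <- simulation_config(n_samples = 5, n_sites = 10,
                           panel_site_fraction = 0.6,
                           n_panel_only_sites = 3, seed = 13)
  truth <- generate_truth(cfg)
  panel <- simulate_panel_callset(truth, cfg)
  m <- match_sites(truth, panel)
  expect_equal(sum(m$in_a & m$in_b), 6)
  expect_equal(sum(m$in_a & !m$in_b), 4)
  expect_equal(sum(!m$in_a & m$in_b), 3)
})

test_that("all-sub-threshold call rates leave zero evaluated panel calls", {
  cfg <- simulation_config(n_samples = 8, n_sites = 6,
                           panel_call_rate_params = list(mean = 40, sd = 1),
                           missing_truth_rate = 0, seed = 3)
  truth <- generate_truth(cfg)
  test <- simulate_test_callset(truth, cfg)
  panel <- simulate_panel_callset(truth, cfg)
  rep <- build_stratified_report(test, panel)
  expect_equal(rep$relaxed$n_evaluated, 0)
  expect_true(is.na(rep$relaxed$concordance_rate))
})
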