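# Compact builders for call tibbles and callsets used across tests.

mk_sites <- function(n, contig = "t1", tranche = "PASS_99") {
  tibble::tibble(
    contig = contig, position = 100L + 10L * seq_len(n),
    ref = "A", alt = "G", rsid = sprintf("rs%03d", seq_len(n)),
    tranche = rep_len(tranche, n)
  )
}

# one call per row of `df`; class_* shorthands: hom_ref/het/hom_alt/none
mk_calls <- function(df, platform) {
  gt <- lapply(df$gt, function(g) {
    if (g == "none") list(a1 = NA_character_, a2 = NA_character_)
    else {
      p <- gt_of_class(g)
      list(a1 = p[1], a2 = p[2])
    }
  })
  df$gt_a1 <- vapply(gt, `[[`, "", "a1")
  df$gt_a2 <- vapply(gt, `[[`, "", "a2")
  df$gt <- NULL
  callset(df, platform)
}

# matched single-site test/truth pair with given genotypes and evidence
mk_pair <- function(test_gt, truth_gt, test_depth = 50L, test_gq = 99,
                    truth_depth = 100L, tranche = "PASS_99") {
  s <- mk_sites(1, tranche = tranche)
  test <- mk_calls(tibble::tibble(
    sample = "S1", contig = s$contig, position = s$position,
    ref = s$ref, alt = s$alt, rsid = s$rsid,
    gt = test_gt, depth = test_depth, gq = test_gq, tranche = tranche
  ), "TEST_WES")
  truth <- mk_calls(tibble::tibble(
    sample = "S1", contig = s$contig, position = s$position,
    ref = s$ref, alt = s$alt, rsid = s$rsid,
    gt = truth_gt, depth = truth_depth
  ), "TRUTH_AMPLICON")
  list(test = test, truth = truth)
}

# random classification tibble with site columns, for property tests
random_classified <- function(n_sites = 6, n_samples = 8) {
  sites <- mk_sites(n_sites)
  grid <- tidyr::expand_grid(i = seq_len(n_sites),
                             sample = sprintf("S%02d", seq_len(n_samples)))
  tibble::tibble(
    sample = grid$sample,
    contig = sites$contig[grid$i], position = sites$position[grid$i],
    ref = sites$ref[grid$i], alt = sites$alt[grid$i],
    classification = sample(call_classes, nrow(grid), replace = TRUE)
  )
}
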