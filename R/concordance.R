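# Per-call classification, FP/FN attribution and stratified summaries.

alt_copies <- function(a1, a2) {
  (!is.na(a1) & a1 == "alt") + (!is.na(a2) & a2 == "alt")
}

has_other <- function(a1, a2) {
  (!is.na(a1) & a1 == "other") | (!is.na(a2) & a2 == "other")
}

gt_multiset <- function(a1, a2) {
  ifelse(is.na(a1), NA_character_,
         paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
}

#' Compare two genotypes at the same site
#'
#' Classifies an evaluable test genotype against a confident truth genotype
#' by counting alternate-allele copies (0, 1 or 2) on each side. Equal allele
#' multisets are `CONCORDANT`. A test call that introduces an alternate
#' copy the truth lacks, without missing any, is a `FALSE_POSITIVE`; one
#' that misses at least one truth alternate copy without introducing any is
#' a `FALSE_NEGATIVE` (so a heterozygous call against a homozygous-variant
#' truth is a false negative: one alternate copy went undetected). Any
#' involvement of an allele foreign to the site, or a simultaneous
#' introduce-and-miss, is `MIXED_DISCORDANT`. Genotype order is ignored.
#'
#' @param test,truth Call tibbles, row-aligned at identical normalized sites,
#'   with columns `gt_a1`, `gt_a2` (and site columns if available, used to
#'   verify alignment). No row may be a no-call.
#' @return Character vector of classifications.
#' @export
compare_genotypes <- function(test, truth) {
  test <- as_tibble(test)
  truth <- as_tibble(truth)
  if (nrow(test) != nrow(truth)) {
    abort("compare_genotypes: test and truth must be row-aligned.")
  }
  if (all(c("contig", "position", "ref", "alt") %in% names(test)) &&
      all(c("contig", "position", "ref", "alt") %in% names(truth))) {
    if (!identical(site_key(test), site_key(truth))) {
      abort("compare_genotypes: site keys differ between test and truth rows.")
    }
  }
  if (any(is.na(test$gt_a1)) || any(is.na(truth$gt_a1))) {
    abort("compare_genotypes: no-calls are not comparable; filter them first.")
  }
  a_test <- alt_copies(test$gt_a1, test$gt_a2)
  a_truth <- alt_copies(truth$gt_a1, truth$gt_a2)
  equal <- gt_multiset(test$gt_a1, test$gt_a2) ==
    gt_multiset(truth$gt_a1, truth$gt_a2)
  foreign <- has_other(test$gt_a1, test$gt_a2) |
    has_other(truth$gt_a1, truth$gt_a2)
  dplyr::case_when(
    equal ~ "CONCORDANT",
    foreign ~ "MIXED_DISCORDANT",
    a_test > a_truth ~ "FALSE_POSITIVE",
    a_test < a_truth ~ "FALSE_NEGATIVE",
    # equal alt dosage but unequal multisets is impossible without a
    # foreign allele in a biallelic diploid model
    TRUE ~ "MIXED_DISCORDANT"
  )
}

#' Classify every test call against a truth or panel callset
#'
#' Runs the full decision cascade over the matched-site universe (sites
#' present in both callsets): (1) a test call whose VQSR tranche is outside
#' the cut is `EXCLUDED_TRANCHE` — stratification precedes every other rule;
#' (2) a test genotype the platform did not emit is `NO_CALL`; (3) a test
#' call failing the depth/quality minima is `NOT_EVALUABLE`; (4) a truth
#' call that is absent, a no-call, or unconfident (amplicon depth below the
#' minimum, or panel call rate at or below the bound) is `MISSING_TRUTH`,
#' with the sub-reason retained; (5) everything else is compared genotype
#' against genotype.
#'
#' @param test A `TEST_WES` callset.
#' @param truth A `TRUTH_AMPLICON` or `PANEL` callset.
#' @param thresholds A [filter_thresholds()] object.
#' @return A tibble with one row per test call at a matched site: site and
#'   sample identifiers, both platforms' genotypes and evidence,
#'   `classification` and `missing_reason`.
#' @export
classify_calls <- function(test, truth, thresholds = filter_thresholds()) {
  truth_platform <- attr(truth, "platform") %||% "TRUTH_AMPLICON"
  matched <- match_sites(test, truth)
  shared <- filter(matched, .data$in_a, .data$in_b)
  test_tbl <- as_tibble(test)
  truth_tbl <- as_tibble(truth)
  test_tbl$.site <- site_key(test_tbl)
  truth_tbl$.site <- site_key(truth_tbl)
  shared_keys <- site_key(shared)

  uni <- filter(test_tbl, .data$.site %in% shared_keys) |>
    select(-"call_rate")  # the panel's call rate comes from the truth side
  tru <- truth_tbl |>
    select(".site", "sample",
           truth_a1 = "gt_a1", truth_a2 = "gt_a2",
           truth_depth = "depth", call_rate = "call_rate")
  uni <- left_join(uni, tru, by = c(".site", "sample"))

  confident <- if (truth_platform == "PANEL") {
    panel_call_confident(
      tibble(call_rate = uni$call_rate), thresholds
    )
  } else {
    truth_call_confident(tibble(depth = uni$truth_depth), thresholds)
  }
  truth_present <- !is.na(uni$truth_a1)
  truth_absent <- !(uni$.site %in% truth_tbl$.site &
                      paste(uni$.site, uni$sample) %in%
                        paste(truth_tbl$.site, truth_tbl$sample))

  stage_excluded <- !in_tranche_cut(uni, thresholds)
  stage_no_call <- is.na(uni$gt_a1)
  stage_not_eval <- !test_call_evaluable(uni, thresholds)
  stage_missing <- truth_absent | !truth_present | !confident

  classification <- dplyr::case_when(
    stage_excluded ~ "EXCLUDED_TRANCHE",
    stage_no_call ~ "NO_CALL",
    stage_not_eval ~ "NOT_EVALUABLE",
    stage_missing ~ "MISSING_TRUTH",
    TRUE ~ NA_character_
  )
  missing_reason <- dplyr::case_when(
    classification != "MISSING_TRUTH" ~ NA_character_,
    truth_absent ~ "truth_absent",
    !truth_present ~ "truth_no_call",
    TRUE ~ if (truth_platform == "PANEL") "low_call_rate" else "low_truth_depth"
  )
  to_compare <- is.na(classification)
  if (any(to_compare)) {
    classification[to_compare] <- compare_genotypes(
      tibble(gt_a1 = uni$gt_a1[to_compare], gt_a2 = uni$gt_a2[to_compare]),
      tibble(gt_a1 = uni$truth_a1[to_compare], gt_a2 = uni$truth_a2[to_compare])
    )
  }

  uni |>
    mutate(
      test_genotype = genotype_string(.data$gt_a1, .data$gt_a2,
                                      .data$ref, .data$alt),
      truth_genotype = genotype_string(.data$truth_a1, .data$truth_a2,
                                       .data$ref, .data$alt),
      classification = classification,
      missing_reason = missing_reason,
      truth_platform = truth_platform
    ) |>
    select("sample", "contig", "position", "ref", "alt", "rsid", "gene",
           "star_allele", "gt_a1", "gt_a2", "truth_a1", "truth_a2",
           "test_genotype", "truth_genotype", "ref_reads", "alt_reads",
           "depth", "gq", "tranche", "truth_depth", "call_rate",
           "classification", "missing_reason", "truth_platform")
}

#' Summarise classified calls into stratified counts
#'
#' Produces the per-stratum bookkeeping block: variant-site and call counts,
#' exclusions by reason, evaluated calls, the discordance decomposition and
#' the concordance rate, defined as
#' `100 * (n_evaluated - n_discordant) / n_evaluated` and left `NA` when no
#' call was evaluated. Count identities (total = low-quality + no-calls +
#' missing-truth + evaluated; evaluated = concordant + discordant;
#' discordant = FP + FN + mixed) are asserted on every run.
#'
#' @param classified Output of [classify_calls()] (or any tibble with a
#'   `classification` column and site columns), covering one stratum.
#' @param stratum Label for the stratum (e.g. `"strict"`, `"relaxed"`).
#' @return A one-row tibble with class `concordance_summary`.
#' @export
summarize_concordance <- function(classified, stratum = "all") {
  cls <- classified$classification
  n_of <- function(k) sum(cls == k)
  in_universe <- cls != "EXCLUDED_TRANCHE"
  n_sites <- if (all(c("contig", "position", "ref", "alt") %in% names(classified))) {
    length(unique(site_key(classified[in_universe, ])))
  } else {
    NA_integer_
  }
  out <- tibble(
    stratum = stratum,
    n_variant_sites = n_sites,
    n_excluded_tranche = n_of("EXCLUDED_TRANCHE"),
    n_total_calls = sum(in_universe),
    n_low_quality = n_of("NOT_EVALUABLE"),
    n_no_calls = n_of("NO_CALL"),
    n_missing_truth = n_of("MISSING_TRUTH"),
    n_evaluated = n_of("CONCORDANT") + n_of("FALSE_POSITIVE") +
      n_of("FALSE_NEGATIVE") + n_of("MIXED_DISCORDANT"),
    n_concordant = n_of("CONCORDANT"),
    n_discordant = n_of("FALSE_POSITIVE") + n_of("FALSE_NEGATIVE") +
      n_of("MIXED_DISCORDANT"),
    n_false_positive = n_of("FALSE_POSITIVE"),
    n_false_negative = n_of("FALSE_NEGATIVE"),
    n_mixed = n_of("MIXED_DISCORDANT"),
    concordance_rate = ifelse(
      n_of("CONCORDANT") + n_of("FALSE_POSITIVE") + n_of("FALSE_NEGATIVE") +
        n_of("MIXED_DISCORDANT") > 0,
      100 * n_of("CONCORDANT") /
        (n_of("CONCORDANT") + n_of("FALSE_POSITIVE") +
           n_of("FALSE_NEGATIVE") + n_of("MIXED_DISCORDANT")),
      NA_real_
    )
  )
  stopifnot(
    out$n_total_calls == out$n_low_quality + out$n_no_calls +
      out$n_missing_truth + out$n_evaluated,
    out$n_evaluated == out$n_concordant + out$n_discordant,
    out$n_discordant == out$n_false_positive + out$n_false_negative +
      out$n_mixed
  )
  class(out) <- c("concordance_summary", class(out))
  out
}

#' Build the two-tranche stratified concordance report
#'
#' Classifies every matched test call twice — under the strict tranche cut
#' (`PASS_99` only) and the relaxed cut (`PASS_99` plus `TRANCHE_99_999`) —
#' and summarises both strata, alongside a per-site table giving each site's
#' tranche membership and per-class call counts under the relaxed universe.
#'
#' @inheritParams classify_calls
#' @return A list with class `stratified_report`: `calls` (per-call tibble
#'   with `class_strict` and `class_relaxed`), `strict` and `relaxed`
#'   summaries, and `per_site`.
#' @export
build_stratified_report <- function(test, truth,
                                    thresholds = filter_thresholds()) {
  th_strict <- thresholds
  th_strict$tranche_cut <- "PASS_99"
  th_relaxed <- thresholds
  th_relaxed$tranche_cut <- c("PASS_99", "TRANCHE_99_999")

  strict_calls <- classify_calls(test, truth, th_strict)
  relaxed_calls <- classify_calls(test, truth, th_relaxed)
  calls <- relaxed_calls |>
    rename(class_relaxed = "classification",
           missing_reason_relaxed = "missing_reason") |>
    mutate(class_strict = strict_calls$classification,
           missing_reason_strict = strict_calls$missing_reason)

  per_site <- calls |>
    group_by(.data$contig, .data$position, .data$ref, .data$alt,
             .data$rsid, .data$gene, .data$tranche) |>
    summarise(
      n_calls = n(),
      n_evaluated = sum(.data$class_relaxed %in%
                          c("CONCORDANT", discordant_classes)),
      n_concordant = sum(.data$class_relaxed == "CONCORDANT"),
      n_discordant = sum(.data$class_relaxed %in% discordant_classes),
      in_strict_cut = .data$tranche[1] == "PASS_99",
      .groups = "drop"
    ) |>
    arrange(.data$contig, .data$position)

  out <- list(
    calls = calls,
    strict = summarize_concordance(strict_calls, "strict"),
    relaxed = summarize_concordance(relaxed_calls, "relaxed"),
    per_site = per_site,
    thresholds = thresholds
  )
  class(out) <- "stratified_report"
  out
}

#' @export
print.stratified_report <- function(x, ...) {
  cat("<stratified_report>\n")
  for (s in list(x$strict, x$relaxed)) {
    cat(sprintf(
      "  %-8s sites %s, calls %d, evaluated %d, discordant %d, concordance %s%%\n",
      s$stratum, s$n_variant_sites, s$n_total_calls, s$n_evaluated,
      s$n_discordant,
      ifelse(is.na(s$concordance_rate), "-", format_rate(s$concordance_rate))
    ))
  }
  invisible(x)
}
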