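# Report writers/readers and fixed-format rate rounding.

#' Round-half-up rate formatting
#'
#' Reported rates use fixed two-decimal formatting with half-up rounding
#' (so 99.5951...% prints as `"99.60"`), matching how concordance rates are
#' conventionally reported; R's own `round()` rounds half to even, which
#' would differ on exact halves.
#'
#' @param x Numeric vector of percentages.
#' @param digits Decimal places (default 2).
#' @return Character vector; `NA` entries print as `""`.
#' @export
format_rate <- function(x, digits = 2) {
  scaled <- floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
  out <- sprintf(paste0("%.", digits, "f"), scaled)
  out[is.na(x)] <- ""
  out
}

#' Write the per-call classification report
#'
#' One TSV row per (sample, site) with both platforms' genotypes, the test
#' evidence, the classification and, for stratified input, both strata's
#' classes.
#'
#' @param classified Output of [classify_calls()] or the `calls` element of
#'   a [build_stratified_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_report <- function(classified, path) {
  readr::write_tsv(as_tibble(classified), path, na = "")
  invisible(path)
}

#' Read back a per-call classification report
#'
#' @param path Path written by [write_call_report()].
#' @return A tibble.
#' @export
read_call_report <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    position = "i", ref_reads = "i", alt_reads = "i", depth = "i",
    gq = "d", truth_depth = "d", call_rate = "d", .default = "c"
  ), na = "")
}

#' Write the stratified summary block
#'
#' Emits the two-column overview (strict and relaxed truth-sensitivity
#' strata) as a labelled TSV: variant sites, total calls, low-quality calls,
#' no-calls, missing-truth calls, evaluated calls, the discordance
#' decomposition, and the concordance rate formatted to two decimals with
#' half-up rounding. Also accepts a single `concordance_summary`.
#'
#' @param summary A `stratified_report` or `concordance_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (inherits(summary, "stratified_report")) {
    summaries <- bind_rows(summary$strict, summary$relaxed)
  } else {
    summaries <- as_tibble(summary)
  }
  labels <- c(
    n_variant_sites = "Variant sites",
    n_excluded_tranche = "Excluded by tranche cut",
    n_total_calls = "Total genotype calls",
    n_low_quality = "Low quality (DP or GQ below minimum)",
    n_no_calls = "No-calls",
    n_missing_truth = "Missing or unconfident truth",
    n_evaluated = "Total calls evaluated",
    n_discordant = "Discordant calls",
    n_false_positive = "False-positives",
    n_false_negative = "False-negatives",
    n_mixed = "Mixed discordant",
    concordance_rate = "Concordance rate (%)"
  )
  block <- tibble(metric = unname(labels))
  for (i in seq_len(nrow(summaries))) {
    vals <- purrr::map_chr(names(labels), function(f) {
      v <- summaries[[f]][i]
      if (f == "concordance_rate") format_rate(v) else as.character(v)
    })
    block[[summaries$stratum[i]]] <- vals
  }
  readr::write_tsv(block, path, na = "")
  invisible(path)
}

#' Write the adjudication attribution report
#'
#' @param adjudicated An `adjudication_result` from [adjudicate()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adjudication_report <- function(adjudicated, path) {
  readr::write_tsv(adjudicated$calls, path, na = "")
  invisible(path)
}

#' Write the off-target annotation report
#'
#' @param annotation An `offtarget_annotation` from [classify_off_target()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_offtarget_report <- function(annotation, path) {
  readr::write_tsv(as_tibble(annotation), path, na = "")
  invisible(path)
}
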