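# Evaluability constants and VQSR tranche vocabulary.

#' VQSR tranche labels
#'
#' The three truth-sensitivity strata a test call can carry, plus
#' `NOT_APPLICABLE` for platforms that do not run VQSR. `PASS_99` marks calls
#' below the 99% truth-sensitivity threshold ("pass-filter"),
#' `TRANCHE_99_999` the 99-99.9% tranche, and `ABOVE_999` anything beyond.
#'
#' @format Character vector of length 4.
#' @export
tranche_levels <- c("PASS_99", "TRANCHE_99_999", "ABOVE_999", "NOT_APPLICABLE")

#' Per-call classification classes
#'
#' The exhaustive categories assigned to each (sample, site) comparison, in
#' cascade order: tranche exclusion, then test-call evaluability, then test
#' no-calls, then missing/unconfident truth, then genotype comparison.
#'
#' @format Character vector of length 8.
#' @export
call_classes <- c(
  "EXCLUDED_TRANCHE", "NOT_EVALUABLE", "NO_CALL", "MISSING_TRUTH",
  "CONCORDANT", "FALSE_POSITIVE", "FALSE_NEGATIVE", "MIXED_DISCORDANT"
)

discordant_classes <- c("FALSE_POSITIVE", "FALSE_NEGATIVE", "MIXED_DISCORDANT")

#' Evaluability thresholds
#'
#' Bundles every quality cut-off the comparison applies. Defaults are the
#' validated exome-profiling rules: test calls need read depth >= 4 and
#' genotype quality >= 10 to be evaluable; amplicon truth calls need depth
#' >= 10 to count as confident; panel calls need a call rate strictly
#' greater than 85%. The tranche cut selects which VQSR strata enter the
#' comparison universe.
#'
#' @param test_dp_min Minimum read depth for a test (exome) call to be
#'   evaluable. Default 4 (inclusive).
#' @param test_gq_min Minimum Phred-scaled genotype quality for a test call.
#'   Default 10 (inclusive).
#' @param truth_dp_min Minimum approximate read depth for a truth (amplicon)
#'   call to be confident. Default 10 (inclusive).
#' @param panel_call_rate_min Panel call-rate bound in percent; calls must
#'   exceed it strictly. Default 85.
#' @param tranche_cut `"strict"` (only `PASS_99`), `"relaxed"` (`PASS_99`
#'   and `TRANCHE_99_999`), or a character vector of tranche labels.
#' @return A list with class `filter_thresholds`.
#' @examples
#' filter_thresholds()
#' filter_thresholds(tranche_cut = "relaxed")
#' @export
filter_thresholds <- function(test_dp_min = 4L, test_gq_min = 10L,
                              truth_dp_min = 10L, panel_call_rate_min = 85,
                              tranche_cut = "strict") {
  if (is.character(tranche_cut) && length(tranche_cut) == 1 &&
      tranche_cut %in% c("strict", "relaxed")) {
    tranche_cut <- switch(tranche_cut,
      strict = "PASS_99",
      relaxed = c("PASS_99", "TRANCHE_99_999")
    )
  }
  if (!all(tranche_cut %in% tranche_levels) || length(tranche_cut) == 0) {
    abort("`tranche_cut` must be a non-empty subset of tranche_levels.")
  }
  if (any(c(test_dp_min, test_gq_min, truth_dp_min, panel_call_rate_min) < 0)) {
    abort("All threshold minima must be >= 0.")
  }
  structure(
    list(
      test_dp_min = as.integer(test_dp_min),
      test_gq_min = as.integer(test_gq_min),
      truth_dp_min = as.integer(truth_dp_min),
      panel_call_rate_min = as.numeric(panel_call_rate_min),
      tranche_cut = tranche_cut
    ),
    class = "filter_thresholds"
  )
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("<filter_thresholds>\n")
  cat("  test call:  DP >=", x$test_dp_min, ", GQ >=", x$test_gq_min, "\n")
  cat("  truth call: DP >=", x$truth_dp_min, "\n")
  cat("  panel call: call rate >", x$panel_call_rate_min, "%\n")
  cat("  tranche cut:", paste(x$tranche_cut, collapse = " + "), "\n")
  invisible(x)
}

#' Read thresholds from a YAML configuration file
#'
#' Recognised keys mirror the arguments of [filter_thresholds()]; absent keys
#' keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `filter_thresholds` object.
#' @export
read_thresholds_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(filter_thresholds))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    abort(paste0("Unknown threshold keys: ", paste(bad, collapse = ", ")))
  }
  do.call(filter_thresholds, cfg)
}
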