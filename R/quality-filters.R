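# Evaluability rules, as pure vectorized predicates over call tibbles.
# All inequality directions follow the validated rules literally (D11):
# exclusion is strict "<" for test DP/GQ, truth depth is inclusive
# "at least", the panel call-rate bound is strictly ">".

#' Is a test (exome) call evaluable?
#'
#' A test call is evaluable when its read depth and genotype quality both
#' meet the minima (`DP >= test_dp_min` and `GQ >= test_gq_min`); a call with
#' absent depth or GQ is not evaluable. Total function: never errors.
#'
#' @param calls A call tibble (rows with platform `TEST_WES`).
#' @param thresholds A [filter_thresholds()] object.
#' @return Logical vector, one element per call.
#' @export
test_call_evaluable <- function(calls, thresholds = filter_thresholds()) {
  dp <- calls$depth
  gq <- calls$gq
  !is.na(dp) & !is.na(gq) &
    dp >= thresholds$test_dp_min & gq >= thresholds$test_gq_min
}

#' Is a test call inside the tranche cut?
#'
#' `TRUE` when the call's VQSR tranche belongs to the configured cut: the
#' strict cut admits only `PASS_99` (below the 99% truth-sensitivity
#' threshold), the relaxed cut also admits `TRANCHE_99_999`.
#'
#' @inheritParams test_call_evaluable
#' @return Logical vector.
#' @export
in_tranche_cut <- function(calls, thresholds = filter_thresholds()) {
  calls$tranche %in% thresholds$tranche_cut
}

#' Is a truth (amplicon) call confident?
#'
#' Truth calls must carry an approximate read depth of at least
#' `truth_dp_min` (default 10-fold); absent depth is not confident.
#'
#' @inheritParams test_call_evaluable
#' @return Logical vector.
#' @export
truth_call_confident <- function(calls, thresholds = filter_thresholds()) {
  dp <- calls$depth
  !is.na(dp) & dp >= thresholds$truth_dp_min
}

#' Is a panel call confident?
#'
#' Panel calls qualify when their call rate strictly exceeds
#' `panel_call_rate_min` percent (default 85); an absent call rate fails.
#'
#' @inheritParams test_call_evaluable
#' @return Logical vector.
#' @export
panel_call_confident <- function(calls, thresholds = filter_thresholds()) {
  cr <- calls$call_rate
  !is.na(cr) & cr > thresholds$panel_call_rate_min
}
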