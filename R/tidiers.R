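# broom-style tidiers for result objects.

#' Tidy a concordance summary
#'
#' @param x A `concordance_summary`.
#' @param ... Unused.
#' @return A long tibble with `stratum`, `metric`, `value`.
#' @method tidy concordance_summary
#' @export
tidy.concordance_summary <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(-"stratum", names_to = "metric", values_to = "value")
}

#' @rdname tidy.concordance_summary
#' @method glance concordance_summary
#' @export
glance.concordance_summary <- function(x, ...) {
  as_tibble(x)[, c("stratum", "n_variant_sites", "n_evaluated",
                   "n_discordant", "concordance_rate")]
}

#' Tidy a stratified report
#'
#' `tidy()` returns the per-site table; `glance()` one row per stratum with
#' the headline counts and rate.
#'
#' @param x A `stratified_report` from [build_stratified_report()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stratified_report
#' @export
tidy.stratified_report <- function(x, ...) {
  x$per_site
}

#' @rdname tidy.stratified_report
#' @method glance stratified_report
#' @export
glance.stratified_report <- function(x, ...) {
  bind_rows(glance(x$strict), glance(x$relaxed))
}

#' Tidy an adjudication result
#'
#' `tidy()` returns the adjudicated calls; `glance()` the attribution
#' tallies.
#'
#' @param x An `adjudication_result` from [adjudicate()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy adjudication_result
#' @export
tidy.adjudication_result <- function(x, ...) {
  x$calls
}

#' @rdname tidy.adjudication_result
#' @method glance adjudication_result
#' @export
glance.adjudication_result <- function(x, ...) {
  tidyr::pivot_wider(x$counts, names_from = "attribution",
                     values_from = "n", values_fill = 0L)
}
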