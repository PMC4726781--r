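# ggplot2 displays for the result types.

#' Plot classification counts per stratum
#'
#' Stacked per-class call counts for the strict and relaxed tranche cuts,
#' showing where the relaxed universe picks up extra (and typically more
#' discordant) calls.
#'
#' @param object A `stratified_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stratified_report
#' @export
autoplot.stratified_report <- function(object, ...) {
  long <- bind_rows(
    mutate(as_tibble(object$strict), stratum = "strict"),
    mutate(as_tibble(object$relaxed), stratum = "relaxed")
  ) |>
    select("stratum", "n_low_quality", "n_no_calls", "n_missing_truth",
           "n_concordant", "n_discordant") |>
    tidyr::pivot_longer(-"stratum", names_to = "class", values_to = "n") |>
    mutate(class = sub("^n_", "", .data$class),
           stratum = factor(.data$stratum, c("strict", "relaxed")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$n,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Tranche cut", y = "Genotype calls", fill = NULL,
                  title = "Call classification by truth-sensitivity stratum") +
    ggplot2::theme_minimal()
}

#' Plot aggregate coverage against distance to the nearest target
#'
#' Per-site aggregate depth versus distance, with the padding radius and
#' the low-coverage threshold marked. Uncapturable sites (no target on
#' their contig) are omitted.
#'
#' @param object An `offtarget_annotation` with an `aggregate_depth`
#'   column.
#' @param low_coverage_threshold Horizontal reference line (default 150).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot offtarget_annotation
#' @export
autoplot.offtarget_annotation <- function(object,
                                          low_coverage_threshold = 150, ...) {
  padding <- attr(object, "padding") %||% 100
  df <- as_tibble(object) |> filter(is.finite(.data$distance))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$distance,
                                   y = .data$aggregate_depth)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category)) +
    ggplot2::geom_vline(xintercept = padding, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = low_coverage_threshold,
                        linetype = "dotted") +
    ggplot2::labs(x = "Distance to nearest target (bases)",
                  y = "Aggregate depth (all samples)", colour = NULL,
                  title = "Coverage by distance from capture targets") +
    ggplot2::theme_minimal()
}

#' Plot binned coverage-by-distance summaries
#'
#' @param object A `coverage_by_distance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coverage_by_distance
#' @export
autoplot.coverage_by_distance <- function(object, ...) {
  thr <- attr(object, "low_coverage_threshold") %||% 150
  df <- as_tibble(object) |>
    mutate(bin = factor(.data$bin, levels = .data$bin))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$median_depth,
                                   fill = .data$low_coverage)) +
    ggplot2::geom_col() +
    ggplot2::geom_point(ggplot2::aes(y = .data$max_depth), shape = 4) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dotted") +
    ggplot2::labs(x = "Distance bin (bases)", y = "Aggregate depth",
                  fill = "Low coverage",
                  title = "Median (bars) and maximum (crosses) depth by distance bin") +
    ggplot2::theme_minimal()
}
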