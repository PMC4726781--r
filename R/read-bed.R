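# Capture-target interval reading (BED3) and convention conversion.

#' Read capture-target intervals from a BED file
#'
#' BED intervals are 0-based half-open; they are converted on read to the
#' 1-based closed convention used everywhere in memory, then merged and
#' sorted per contig (IRanges reduction), so downstream distance arithmetic
#' can assume non-overlapping sorted targets. `track`/`browser`/comment
#' lines are skipped. An empty file yields an empty, valid interval set.
#'
#' @param path Path to a BED3+ file.
#' @return A tibble with class `target_intervals`: `contig`, `start`, `end`
#'   (1-based closed).
#' @export
read_target_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  empty <- tibble(contig = character(), start = integer(), end = integer())
  if (!any(keep)) {
    return(structure(empty, class = c("target_intervals", class(empty))))
  }
  idx <- which(keep)
  parsed <- purrr::map(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3) {
      abort(paste0("Malformed BED line ", i, ": fewer than 3 columns."))
    }
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s >= e) {
      abort(paste0("Malformed interval at BED line ", i, ": start (", f[2],
                   ") must be a number strictly below end (", f[3], ")."))
    }
    tibble(contig = f[1], start = s + 1L, end = e)
  })
  raw <- bind_rows(parsed)
  merged <- raw |>
    group_by(.data$contig) |>
    dplyr::reframe({
      red <- IRanges::reduce(IRanges::IRanges(start = .data$start, end = .data$end))
      tibble(start = IRanges::start(red), end = IRanges::end(red))
    }) |>
    arrange(.data$contig, .data$start)
  structure(as_tibble(merged),
            class = c("target_intervals", class(empty)))
}

#' Write target intervals back to BED3
#'
#' Inverse of [read_target_bed()]: 1-based closed intervals are emitted as
#' 0-based half-open lines.
#'
#' @param targets A `target_intervals` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_bed <- function(targets, path) {
  lines <- sprintf("%s\t%d\t%d", targets$contig, targets$start - 1L, targets$end)
  writeLines(lines, path)
  invisible(path)
}
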