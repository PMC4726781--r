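# The callset container: a tibble of per-sample, per-site genotype calls.

platform_levels <- c("TEST_WES", "TRUTH_AMPLICON", "PANEL", "SANGER")

call_columns <- c(
  "sample", "contig", "position", "ref", "alt", "rsid", "gene", "star_allele",
  "gt_a1", "gt_a2", "ref_reads", "alt_reads", "depth", "gq", "tranche",
  "call_rate", "platform"
)

#' Construct a callset
#'
#' A callset is a tibble with one row per (sample, site) genotype call on a
#' single platform, carrying the quality evidence that platform emits.
#' Genotypes are unordered, unphased and diploid: `gt_a1`/`gt_a2` take values
#' `"ref"`, `"alt"` or `"other"` (an allele that is neither this site's ref
#' nor alt, arising from multiallelic projection), and are both `NA` for a
#' no-call. `depth` is taken from the platform's DP when available and
#' reconstructed as `ref_reads + alt_reads` otherwise.
#'
#' @param calls A data frame with at least `sample`, `contig`, `position`,
#'   `ref`, `alt`, `gt_a1`, `gt_a2`. Missing evidence columns are filled
#'   with `NA`.
#' @param platform One of `"TEST_WES"`, `"TRUTH_AMPLICON"`, `"PANEL"`,
#'   `"SANGER"`.
#' @return A tibble with class `callset`.
#' @export
callset <- function(calls, platform) {
  platform <- match.arg(platform, platform_levels)
  calls <- as_tibble(calls)
  required <- c("sample", "contig", "position", "ref", "alt", "gt_a1", "gt_a2")
  missing_cols <- setdiff(required, names(calls))
  if (length(missing_cols)) {
    abort(paste0("callset is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  for (col in setdiff(call_columns, names(calls))) {
    calls[[col]] <- switch(col,
      position = NA_integer_, ref_reads = NA_integer_, alt_reads = NA_integer_,
      depth = NA_integer_, gq = NA_real_, call_rate = NA_real_,
      tranche = "NOT_APPLICABLE", NA_character_
    )
  }
  calls$platform <- platform
  calls$position <- as.integer(calls$position)
  calls$ref_reads <- as.integer(calls$ref_reads)
  calls$alt_reads <- as.integer(calls$alt_reads)
  # D10: reconstruct DP from per-allele counts when absent
  calls$depth <- as.integer(ifelse(
    is.na(calls$depth), calls$ref_reads + calls$alt_reads, calls$depth
  ))
  calls <- calls[, call_columns]
  validate_callset(calls)
  structure(calls, class = c("callset", class(as_tibble(calls))),
            platform = platform)
}

validate_callset <- function(calls) {
  gt_ok <- is.na(calls$gt_a1) | calls$gt_a1 %in% c("ref", "alt", "other")
  gt_ok2 <- is.na(calls$gt_a2) | calls$gt_a2 %in% c("ref", "alt", "other")
  if (!all(gt_ok & gt_ok2)) abort("gt_a1/gt_a2 must be 'ref', 'alt', 'other' or NA.")
  # diploid, unphased: a half-missing genotype is not representable (D3)
  half <- xor(is.na(calls$gt_a1), is.na(calls$gt_a2))
  if (any(half)) abort("Half-missing genotypes are not supported (diploid model).")
  if (!all(calls$tranche %in% tranche_levels)) {
    abort("tranche must be one of tranche_levels.")
  }
  key <- paste(calls$sample, calls$contig, calls$position, calls$ref, calls$alt)
  if (anyDuplicated(key)) {
    abort("Duplicate (sample, site) calls in callset.")
  }
  invisible(calls)
}

#' @export
print.callset <- function(x, ...) {
  cat("<callset:", attr(x, "platform"), ">", nrow(x), "calls,",
      nrow(sites_of(x)), "sites,", length(unique(x$sample)), "samples\n")
  NextMethod()
}

# Subsetting a callset with dplyr verbs drops to a plain tibble; that is
# fine everywhere downstream, which only needs the columns.

#' Site roster of a callset
#'
#' @param x A callset (or any call tibble).
#' @return A tibble of distinct sites (contig, position, ref, alt, rsid,
#'   gene, star_allele).
#' @export
sites_of <- function(x) {
  distinct(as_tibble(x)[, c("contig", "position", "ref", "alt", "rsid",
                            "gene", "star_allele")])
}

site_key <- function(x) {
  paste(x$contig, x$position, x$ref, x$alt, sep = ":")
}

genotype_string <- function(gt_a1, gt_a2, ref, alt) {
  base <- function(a) ifelse(a == "ref", ref, ifelse(a == "alt", alt, "?"))
  ifelse(is.na(gt_a1), "./.", paste0(base(gt_a1), "/", base(gt_a2)))
}
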