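# Allele normalization and cross-platform site matching.

assert_dna <- function(allele, what = "allele") {
  bad <- !grepl("^[ACGT]+$", allele)
  if (any(bad)) {
    abort(paste0(
      "Malformed ", what, "(s): ",
      paste(unique(allele[bad]), collapse = ", "),
      " (alleles must be non-empty uppercase A/C/G/T strings)."
    ))
  }
  invisible(allele)
}

#' Normalize variant sites to their minimal local representation
#'
#' Canonicalises each site so that VCF-styled and panel-styled spellings of
#' the same variant compare equal: the shared allele suffix is trimmed, then
#' the shared prefix is trimmed (keeping both alleles non-empty, so an indel
#' retains one shared leading base), and the position is advanced by the
#' number of prefix bases removed. Idempotent. No reference-genome
#' left-alignment is attempted: normalization is purely local trimming, so
#' two platforms must declare an indel at the same coordinate to match.
#'
#' @param sites A data frame with columns `position`, `ref`, `alt` (other
#'   columns pass through).
#' @return The input tibble with `position`, `ref`, `alt` normalized.
#' @examples
#' normalize_site(tibble::tibble(position = 100L, ref = "AT", alt = "AC"))
#' @export
normalize_site <- function(sites) {
  sites <- as_tibble(sites)
  if (nrow(sites) == 0) return(sites)
  assert_dna(sites$ref, "ref allele")
  assert_dna(sites$alt, "alt allele")
  if (any(sites$ref == sites$alt)) abort("ref and alt must differ.")
  if (any(sites$position < 1)) abort("position must be >= 1.")
  trimmed <- purrr::pmap(
    list(sites$position, sites$ref, sites$alt),
    function(pos, ref, alt) {
      r <- strsplit(ref, "")[[1]]
      a <- strsplit(alt, "")[[1]]
      while (length(r) > 1 && length(a) > 1 &&
             r[length(r)] == a[length(a)]) {
        r <- r[-length(r)]
        a <- a[-length(a)]
      }
      while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
        r <- r[-1]
        a <- a[-1]
        pos <- pos + 1L
      }
      list(position = as.integer(pos),
           ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
    }
  )
  sites$position <- purrr::map_int(trimmed, "position")
  sites$ref <- purrr::map_chr(trimmed, "ref")
  sites$alt <- purrr::map_chr(trimmed, "alt")
  sites
}

#' Split a multiallelic record into biallelic sites
#'
#' Each alternate allele becomes its own normalized biallelic site. Diploid
#' allele codes are projected onto each site: code 0 maps to `"ref"`, the
#' site's own alt index to `"alt"`, and any other alternate allele to
#' `"other"`, so cross-allele disagreements stay visible downstream instead
#' of silently collapsing to reference.
#'
#' @param record A list with `contig`, `position`, `ref`, `alts` (character
#'   vector, length >= 1), and optionally `rsid` and `genotypes`, a data
#'   frame with columns `sample`, `a1`, `a2` holding VCF allele indices
#'   (0 = ref, 1.. = alts, `NA` = missing).
#' @return A list with one element per alternate allele, each a list holding
#'   `site` (one-row tibble) and `calls` (tibble with `sample`, `gt_a1`,
#'   `gt_a2`), empty when no genotypes were supplied.
#' @export
split_multiallelic <- function(record) {
  if (length(record$alts) == 0) abort("Record carries no alternate allele.")
  gts <- record$genotypes
  purrr::imap(record$alts, function(alt_allele, j) {
    site <- normalize_site(tibble(
      contig = record$contig,
      position = as.integer(record$position),
      ref = record$ref,
      alt = alt_allele,
      rsid = record$rsid %||% NA_character_
    ))
    calls <- NULL
    if (!is.null(gts)) {
      project <- function(code) {
        dplyr::case_when(
          is.na(code) ~ NA_character_,
          code == 0 ~ "ref",
          code == j ~ "alt",
          TRUE ~ "other"
        )
      }
      calls <- tibble(
        sample = gts$sample,
        gt_a1 = project(gts$a1),
        gt_a2 = project(gts$a2)
      )
    }
    list(site = site, calls = calls)
  })
}

#' Match sites across two callsets
#'
#' Builds the union of normalized sites with per-callset membership flags.
#' The primary key is (contig, position, ref, alt); a site that carries only
#' an rsID and no coordinates on one side is matched by rsID as a fallback,
#' and each fallback match is reported via a message.
#'
#' @param a,b Callsets (or site tibbles).
#' @return A tibble of sites covering the union, with logical columns
#'   `in_a` and `in_b`.
#' @export
match_sites <- function(a, b) {
  sa <- if (all(c("gt_a1", "sample") %in% names(a))) sites_of(a) else as_tibble(a)
  sb <- if (all(c("gt_a1", "sample") %in% names(b))) sites_of(b) else as_tibble(b)
  for (nm in c("rsid", "gene", "star_allele")) {
    if (!nm %in% names(sa)) sa[[nm]] <- NA_character_
    if (!nm %in% names(sb)) sb[[nm]] <- NA_character_
  }
  check_rsid_conflicts(bind_rows(sa, sb))

  sa$.key <- ifelse(is.na(sa$position), NA_character_, site_key(sa))
  sb$.key <- ifelse(is.na(sb$position), NA_character_, site_key(sb))

  matched_key <- intersect(stats::na.omit(sa$.key), stats::na.omit(sb$.key))
  # rsID fallback only where one side lacks coordinates (D5)
  coordless <- c(sa$rsid[is.na(sa$.key)], sb$rsid[is.na(sb$.key)])
  fallback_rsids <- intersect(
    stats::na.omit(coordless),
    stats::na.omit(c(sa$rsid, sb$rsid))
  )
  fallback_rsids <- setdiff(fallback_rsids, NA)
  # an rsID already matched by coordinates needs no fallback
  fallback_rsids <- setdiff(
    fallback_rsids,
    sa$rsid[sa$.key %in% matched_key]
  )

  sa$.match <- ifelse(!is.na(sa$rsid) & sa$rsid %in% fallback_rsids,
                      paste0("rsid:", sa$rsid), sa$.key)
  sb$.match <- ifelse(!is.na(sb$rsid) & sb$rsid %in% fallback_rsids,
                      paste0("rsid:", sb$rsid), sb$.key)
  if (length(fallback_rsids)) {
    inform(paste0("match_sites: matched by rsID fallback: ",
                  paste(fallback_rsids, collapse = ", ")))
  }

  merged <- full_join(
    mutate(sa, in_a = TRUE),
    mutate(sb, in_b = TRUE),
    by = ".match", suffix = c("", ".b"), na_matches = "never"
  )
  # prefer the coordinate-bearing side's fields
  for (nm in c("contig", "position", "ref", "alt", "rsid", "gene", "star_allele")) {
    bnm <- paste0(nm, ".b")
    if (bnm %in% names(merged)) {
      merged[[nm]] <- dplyr::coalesce(merged[[nm]], merged[[bnm]])
    }
  }
  merged$in_a <- !is.na(merged$in_a)
  merged$in_b <- !is.na(merged$in_b)
  out <- merged[, c("contig", "position", "ref", "alt", "rsid", "gene",
                    "star_allele", "in_a", "in_b")]
  arrange(out, .data$contig, .data$position, .data$rsid)
}

check_rsid_conflicts <- function(sites) {
  with_both <- filter(sites, !is.na(.data$rsid), !is.na(.data$position))
  if (nrow(with_both) == 0) return(invisible(NULL))
  conflicts <- with_both |>
    distinct(.data$rsid, .data$contig, .data$position, .data$ref, .data$alt) |>
    count(.data$rsid) |>
    filter(.data$n > 1)
  if (nrow(conflicts)) {
    abort(paste0(
      "Ambiguous site(s): rsID(s) mapped to conflicting coordinates: ",
      paste(conflicts$rsid, collapse = ", ")
    ))
  }
  invisible(NULL)
}
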