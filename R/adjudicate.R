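# Sanger-style adjudication of discordant calls.

#' Adjudicate discordant calls against an orthogonal genotype
#'
#' For each discordant (sample, site) pair that has an adjudication record
#' (typically a Sanger genotype), attributes the error to the platform whose
#' genotype disagrees with the adjudicated alleles: `TEST_CORRECT` when the
#' test genotype matches Sanger and the truth/panel genotype does not,
#' `TRUTH_CORRECT` for the converse, `BOTH_WRONG` when neither matches.
#' Original classifications are preserved, never overwritten. Records
#' supplied for non-discordant pairs are ignored with a warning.
#'
#' @param classified Output of [classify_calls()] (or the `calls` element of
#'   a [build_stratified_report()], using the relaxed classification).
#' @param adjudication A tibble of adjudication records as returned by
#'   [read_adjudication_table()]: `sample`, site identifiers (`rsid` and/or
#'   coordinates) and adjudicated `gt_a1`, `gt_a2` in ref/alt coding.
#' @return A list with class `adjudication_result`: `calls`, the discordant
#'   rows with an `attribution` column, and `counts`, attribution tallies
#'   per tranche stratum.
#' @export
adjudicate <- function(classified, adjudication) {
  classified <- as_tibble(classified)
  class_col <- if ("classification" %in% names(classified)) {
    "classification"
  } else if ("class_relaxed" %in% names(classified)) {
    "class_relaxed"
  } else {
    abort("adjudicate: no classification column found.")
  }
  adjudication <- as_tibble(adjudication)
  adjudication$.id <- seq_len(nrow(adjudication))

  disc <- classified[classified[[class_col]] %in% discordant_classes, ]
  # match adjudication rows to discordant calls: coordinates first, rsID next
  adj_key <- if (all(c("contig", "position", "ref", "alt") %in%
                     names(adjudication)) &&
                 !all(is.na(adjudication$position))) {
    paste(site_key(adjudication), adjudication$sample)
  } else {
    rep(NA_character_, nrow(adjudication))
  }
  disc_key <- paste(site_key(disc), disc$sample)
  idx <- match(disc_key, adj_key)
  if ("rsid" %in% names(adjudication)) {
    rs_key <- paste(adjudication$rsid, adjudication$sample)
    idx2 <- match(paste(disc$rsid, disc$sample), rs_key)
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }

  matched_ids <- stats::na.omit(adjudication$.id[idx])
  orphan <- setdiff(adjudication$.id, matched_ids)
  if (length(orphan)) {
    warn(paste0(
      "adjudicate: ", length(orphan),
      " adjudication record(s) do not correspond to a discordant call; ignored."
    ))
  }

  got <- !is.na(idx)
  adj_a1 <- adjudication$gt_a1[idx]
  adj_a2 <- adjudication$gt_a2[idx]
  sanger <- gt_multiset(adj_a1, adj_a2)
  test_ms <- gt_multiset(disc$gt_a1, disc$gt_a2)
  truth_ms <- gt_multiset(disc$truth_a1, disc$truth_a2)
  attribution <- dplyr::case_when(
    !got ~ "UNADJUDICATED",
    test_ms == sanger & truth_ms != sanger ~ "TEST_CORRECT",
    truth_ms == sanger & test_ms != sanger ~ "TRUTH_CORRECT",
    test_ms != sanger & truth_ms != sanger ~ "BOTH_WRONG",
    TRUE ~ "UNADJUDICATED"
  )
  calls <- mutate(disc,
                  sanger_genotype = ifelse(
                    got, genotype_string(adj_a1, adj_a2, disc$ref, disc$alt),
                    NA_character_),
                  attribution = attribution)
  counts <- calls |>
    count(.data$tranche, .data$attribution, name = "n") |>
    arrange(.data$tranche, .data$attribution)
  structure(list(calls = calls, counts = counts),
            class = "adjudication_result")
}

#' @export
print.adjudication_result <- function(x, ...) {
  cat("<adjudication_result>", nrow(x$calls), "discordant call(s)\n")
  print(x$counts)
  invisible(x)
}
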