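# Bundled example data.

#' Paths to bundled example files
#'
#' @param file File name within the package's `extdata`, or `NULL` to list
#'   available files.
#' @return A path, or a character vector of file names.
#' @export
pgx_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pgxconcord")))
  }
  path <- system.file("extdata", file, package = "pgxconcord")
  if (path == "") abort(paste0("No bundled example file called ", file, "."))
  path
}

#' Bundled discordant-call worked examples
#'
#' Reconstructs, as ready-made callsets, the discordant pass-filter calls of
#' a published 36-sample exome validation: the `"amplicon"` set holds the
#' three exome-vs-amplicon discordants (all counted against the exome
#' platform before adjudication; Sanger showed two of the three exome calls
#' were right), the `"panel"` set the eight exome-vs-panel discordants
#' (Sanger confirmed all eight exome calls). Sample identifiers, positions
#' and the panel set's ref/alt bases are synthetic — the sources print only
#' rsIDs, zygosities and quality metrics — so these fixtures pin the
#' classification and adjudication logic, not genomic coordinates.
#'
#' @param comparison `"amplicon"` or `"panel"`.
#' @return A list with `test` (a `TEST_WES` callset), `truth` (the amplicon
#'   or panel callset) and `adjudication` (a Sanger record tibble for
#'   [adjudicate()]).
#' @export
example_validation_calls <- function(comparison = c("amplicon", "panel")) {
  comparison <- match.arg(comparison)
  file <- switch(comparison,
                 amplicon = "miseq_discordant_calls.tsv",
                 panel = "panel_discordant_calls.tsv")
  tbl <- readr::read_tsv(pgx_example(file),
                         col_types = readr::cols(.default = "c"))
  # synthetic coordinates: one locus per rsID, stable across platforms
  rsids <- unique(tbl$rsid)
  pos <- setNames(1000L + 100L * seq_along(rsids), rsids)
  rows <- seq_len(nrow(tbl)) + 1L
  base <- tibble(
    sample = tbl$sample_id, contig = "fixture1",
    position = unname(pos[tbl$rsid]),
    ref = tbl$ref, alt = tbl$alt, rsid = tbl$rsid, gene = tbl$gene
  )
  gt <- function(col) {
    pairs <- parse_allele_pair(tbl[[col]], tbl$ref, tbl$alt, rows, file)
    list(a1 = purrr::map_chr(pairs, "a1"), a2 = purrr::map_chr(pairs, "a2"))
  }
  tg <- gt("test_genotype")
  test <- callset(
    mutate(base,
           gt_a1 = tg$a1, gt_a2 = tg$a2,
           ref_reads = as.integer(tbl$ref_reads),
           alt_reads = as.integer(tbl$alt_reads),
           gq = as.numeric(tbl$gq), tranche = "PASS_99"),
    "TEST_WES"
  )
  og <- gt("truth_genotype")
  truth <- if (comparison == "amplicon") {
    callset(mutate(base, gt_a1 = og$a1, gt_a2 = og$a2, depth = 100L),
            "TRUTH_AMPLICON")
  } else {
    callset(mutate(base, gt_a1 = og$a1, gt_a2 = og$a2, call_rate = 95),
            "PANEL")
  }
  sg <- gt("sanger_genotype")
  adjudication <- mutate(base, gt_a1 = sg$a1, gt_a2 = sg$a2)
  list(test = test, truth = truth, adjudication = adjudication)
}

#' Synthetic callsets reproducing the published call bookkeeping
#'
#' Builds a matched pair of exome-test and amplicon-truth callsets whose
#' classification bookkeeping reproduces, exactly, the call accounting of a
#' published 36-sample exome validation of CYP2D6/CYP2C19: 27 pass-filter
#' sites carrying 943 calls of which 202 are excluded (insufficient
#' quality, no-calls, or missing truth) and 741 evaluated with 3 discordant
#' (all false negatives); plus 16 tranche sites whose additional 569 calls
#' bring the relaxed universe to 1512 generated / 1249 evaluated / 136
#' discordant. Genotypes, coordinates and the within-excluded split are
#' synthetic: only the published totals are pinned.
#'
#' @return A list with `test` and `truth` callsets.
#' @export
example_bookkeeping_callsets <- function() {
  n_samples <- 36L
  samples <- sprintf("S%03d", seq_len(n_samples))
  site_tbl <- tibble(
    contig = "fx1",
    position = 1000L + 10L * seq_len(43L),
    ref = "A", alt = "G",
    rsid = sprintf("rsfx%02d", seq_len(43L)),
    tranche = rep(c("PASS_99", "TRANCHE_99_999"), times = c(27L, 16L))
  )
  # per-stratum class blocks; the running totals are the published figures,
  # the decomposition of the exclusions and of the 133 tranche-only
  # discordants (majority false-positive) is illustrative
  blocks <- list(
    PASS_99 = c(NOT_EVALUABLE = 149L, NO_CALL = 24L, MISSING_TRUTH = 29L,
                FALSE_NEGATIVE = 3L, FALSE_POSITIVE = 0L, CONCORDANT = 738L),
    TRANCHE_99_999 = c(NOT_EVALUABLE = 40L, NO_CALL = 10L,
                       MISSING_TRUTH = 11L, FALSE_NEGATIVE = 13L,
                       FALSE_POSITIVE = 120L, CONCORDANT = 375L)
  )
  test_rows <- list()
  truth_rows <- list()
  for (tr in names(blocks)) {
    sites <- site_tbl[site_tbl$tranche == tr, ]
    slots <- tidyr::expand_grid(site_idx = seq_len(nrow(sites)),
                                sample = samples)
    n_calls <- sum(blocks[[tr]])
    slots <- slots[seq_len(n_calls), ]
    cls <- rep(names(blocks[[tr]]), times = blocks[[tr]])
    s <- sites[slots$site_idx, ]
    test_gt <- dplyr::case_when(
      cls == "NO_CALL" ~ "none",
      cls == "FALSE_NEGATIVE" ~ "hom_ref",
      cls == "FALSE_POSITIVE" ~ "het",
      TRUE ~ "het"
    )
    truth_gt <- dplyr::case_when(
      cls == "FALSE_NEGATIVE" ~ "het",
      cls == "FALSE_POSITIVE" ~ "hom_ref",
      TRUE ~ "het"
    )
    test_rows[[tr]] <- tibble(
      sample = slots$sample, contig = s$contig, position = s$position,
      ref = s$ref, alt = s$alt, rsid = s$rsid,
      gt_a1 = dplyr::case_when(test_gt == "none" ~ NA_character_,
                               TRUE ~ "ref"),
      gt_a2 = dplyr::case_when(test_gt == "none" ~ NA_character_,
                               test_gt == "het" ~ "alt", TRUE ~ "ref"),
      depth = ifelse(cls == "NOT_EVALUABLE", 2L,
                     ifelse(cls == "NO_CALL", NA_integer_, 50L)),
      gq = ifelse(cls == "NOT_EVALUABLE", 5,
                  ifelse(cls == "NO_CALL", NA_real_, 99)),
      tranche = tr
    )
    keep_truth <- cls != "MISSING_TRUTH"
    truth_rows[[tr]] <- tibble(
      sample = slots$sample[keep_truth], contig = s$contig[keep_truth],
      position = s$position[keep_truth], ref = s$ref[keep_truth],
      alt = s$alt[keep_truth], rsid = s$rsid[keep_truth],
      gt_a1 = "ref",
      gt_a2 = ifelse(truth_gt[keep_truth] == "het", "alt", "ref"),
      depth = 100L
    )
  }
  list(
    test = callset(bind_rows(test_rows), "TEST_WES"),
    truth = callset(bind_rows(truth_rows), "TRUTH_AMPLICON")
  )
}
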