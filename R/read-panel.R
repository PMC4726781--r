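# Genotyping-panel export and adjudication tables (TSV).

parse_allele_pair <- function(genotype, ref, alt, rows, context) {
  split <- strsplit(ifelse(is.na(genotype), "", genotype), "/", fixed = TRUE)
  purrr::pmap(list(split, ref, alt, rows), function(g, r, a, row) {
    if (length(g) == 0 || all(g == "")) {
      return(list(a1 = NA_character_, a2 = NA_character_))
    }
    if (length(g) == 1) g <- c(g, g)  # "A" shorthand for homozygous
    if (length(g) != 2) {
      abort(paste0(context, " row ", row, ": genotype must be two '/'-separated alleles."))
    }
    coded <- ifelse(g == r, "ref", ifelse(g == a, "alt", NA))
    if (any(is.na(coded))) {
      abort(paste0(
        context, " row ", row, ": allele(s) ",
        paste(g[is.na(coded)], collapse = ","),
        " match neither ref (", r, ") nor alt (", a, ")."
      ))
    }
    list(a1 = coded[1], a2 = coded[2])
  })
}

#' Read a genotyping-panel export table into a callset
#'
#' Consumes the tab-delimited genotype export of an iPLEX-style multiplexed
#' panel: one row per (sample, variant) with the typed genotype and the
#' assay's per-call call-rate percentage. Columns: `sample_id`, `rsid`,
#' optional `contig`/`position`, `ref`, `alt`, `genotype` (e.g. `"G/A"`,
#' empty for a no-call), `call_rate`. A genotype letter matching neither
#' ref nor alt raises an error naming the row. A documented example ships
#' in `inst/extdata/panel_example.tsv`.
#'
#' @param path Path to the TSV file.
#' @return A [callset()] with platform `PANEL`.
#' @export
read_panel_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  required <- c("sample_id", "rsid", "ref", "alt", "genotype", "call_rate")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("Panel table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pairs <- parse_allele_pair(tbl$genotype, tbl$ref, tbl$alt,
                             seq_len(nrow(tbl)) + 1L, "Panel table")
  calls <- tibble(
    sample = tbl$sample_id,
    contig = if ("contig" %in% names(tbl)) tbl$contig else NA_character_,
    position = if ("position" %in% names(tbl)) as.integer(tbl$position) else NA_integer_,
    ref = tbl$ref, alt = tbl$alt, rsid = tbl$rsid,
    gene = if ("gene" %in% names(tbl)) tbl$gene else NA_character_,
    gt_a1 = purrr::map_chr(pairs, "a1"),
    gt_a2 = purrr::map_chr(pairs, "a2"),
    call_rate = as.numeric(tbl$call_rate)
  )
  # normalize only coordinate-bearing rows; rsID-only rows have no position
  # to advance and panel assays are single-base, already minimal
  has_pos <- !is.na(calls$position)
  if (any(has_pos)) {
    calls[has_pos, c("position", "ref", "alt")] <-
      normalize_site(calls[has_pos, ])[, c("position", "ref", "alt")]
  }
  callset(calls, "PANEL")
}

#' Read a Sanger adjudication table
#'
#' One row per adjudicated (sample, site): `sample_id`, `rsid`, optional
#' `contig`/`position`, `ref`, `alt`, `genotype` with the Sanger-determined
#' alleles (drawn from the site's ref/alt).
#'
#' @param path Path to the TSV file.
#' @return A tibble of adjudication records with ref/alt-coded `gt_a1`,
#'   `gt_a2`, ready for [adjudicate()].
#' @export
read_adjudication_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  required <- c("sample_id", "rsid", "ref", "alt", "genotype")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    abort(paste0("Adjudication table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  pairs <- parse_allele_pair(tbl$genotype, tbl$ref, tbl$alt,
                             seq_len(nrow(tbl)) + 1L, "Adjudication table")
  tibble(
    sample = tbl$sample_id,
    contig = if ("contig" %in% names(tbl)) tbl$contig else NA_character_,
    position = if ("position" %in% names(tbl)) as.integer(tbl$position) else NA_integer_,
    ref = tbl$ref, alt = tbl$alt, rsid = tbl$rsid,
    gt_a1 = purrr::map_chr(pairs, "a1"),
    gt_a2 = purrr::map_chr(pairs, "a2")
  )
}

#' Write a panel callset back to the panel TSV schema
#'
#' @param cs A `PANEL` [callset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_table <- function(cs, path) {
  calls <- as_tibble(cs)
  base <- function(a, ref, alt) ifelse(a == "ref", ref, alt)
  out <- tibble(
    sample_id = calls$sample,
    rsid = calls$rsid,
    contig = calls$contig,
    position = calls$position,
    ref = calls$ref,
    alt = calls$alt,
    genotype = ifelse(is.na(calls$gt_a1), "",
                      paste0(base(calls$gt_a1, calls$ref, calls$alt), "/",
                             base(calls$gt_a2, calls$ref, calls$alt))),
    call_rate = calls$call_rate,
    gene = calls$gene
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}
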