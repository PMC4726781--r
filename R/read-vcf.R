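# VCF reading (vcfR-backed) and the FILTER -> tranche dialect.

#' Default FILTER-to-tranche dialect
#'
#' Maps VCF FILTER strings to tranche labels: `PASS` or `.` mean the call is
#' below the 99% truth-sensitivity threshold (`PASS_99`); any
#' `VQSRTranche...99.00to99.90` string (SNP or INDEL) means the 99-99.9%
#' tranche; every other non-empty FILTER is treated as beyond 99.9% and a
#' warning is raised, because GATK FILTER spellings vary by version. Supply
#' your own dialect (a named list of regex vectors, names among
#' `tranche_levels`) to extend it.
#'
#' @return Named list of regular-expression vectors.
#' @export
default_tranche_dialect <- function() {
  list(
    PASS_99 = c("^PASS$", "^\\.$", "^$"),
    TRANCHE_99_999 = "^VQSRTranche.*99\\.00to99\\.90$"
  )
}

map_filter_to_tranche <- function(filters, dialect = default_tranche_dialect()) {
  out <- rep(NA_character_, length(filters))
  filters[is.na(filters)] <- "."
  for (tr in names(dialect)) {
    hit <- Reduce(`|`, lapply(dialect[[tr]], grepl, x = filters))
    out[is.na(out) & hit] <- tr
  }
  unknown <- unique(filters[is.na(out)])
  if (length(unknown)) {
    warn(paste0("Unrecognized FILTER string(s) mapped to ABOVE_999: ",
                paste(unknown, collapse = ", ")))
    out[is.na(out)] <- "ABOVE_999"
  }
  out
}

parse_gt_codes <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[is.na(gt) | gt == "." | gt == "./."] <- NA_character_
  parts <- strsplit(gt, "/", fixed = TRUE)
  n_alleles <- lengths(parts)
  if (any(!is.na(gt) & n_alleles != 2)) {
    abort("Non-diploid genotype encountered; only diploid records are supported.")
  }
  code <- function(k) {
    v <- purrr::map_chr(parts, function(p) if (length(p) == 2) p[k] else NA_character_)
    v[v == "."] <- NA
    as.integer(v)
  }
  a1 <- code(1)
  a2 <- code(2)
  # a half-missing diploid genotype (./1) is treated as a no-call
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_
  a2[half] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

#' Read a multi-sample VCF into a callset
#'
#' Parses a VCF 4.x file, splits multiallelic records into normalized
#' biallelic sites, maps FILTER to a VQSR tranche via the dialect, and
#' collects per-genotype evidence: `AD` supplies ref/alt read counts, `DP`
#' the depth (reconstructed from `AD` when absent), `GQ` the genotype
#' quality. `./.` genotypes become no-calls; absent evidence stays `NA`,
#' never zero.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param platform Platform tag for the resulting callset.
#' @param tranche_dialect FILTER dialect, see [default_tranche_dialect()].
#' @return A [callset()].
#' @export
read_vcf_callset <- function(path, platform = "TEST_WES",
                             tranche_dialect = default_tranche_dialect()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(callset(tibble(
      sample = character(), contig = character(), position = integer(),
      ref = character(), alt = character(),
      gt_a1 = character(), gt_a2 = character()
    ), platform))
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    abort("VCF parse error: FORMAT lacks GT in one or more records.")
  }
  samples <- colnames(v@gt)[-1]
  gt_m <- vcfR::extract.gt(v, element = "GT")
  dp_m <- if (any(grepl("(^|:)DP(:|$)", fmt))) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else NULL
  gq_m <- if (any(grepl("(^|:)GQ(:|$)", fmt))) {
    suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  } else NULL
  ad_m <- if (any(grepl("(^|:)AD(:|$)", fmt))) {
    vcfR::extract.gt(v, element = "AD")
  } else NULL

  tranches <- map_filter_to_tranche(fix$FILTER, tranche_dialect)

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    codes <- parse_gt_codes(gt_m[i, , drop = TRUE])
    record <- list(
      contig = fix$CHROM[i], position = as.integer(fix$POS[i]),
      ref = fix$REF[i], alts = alts,
      rsid = ifelse(is.na(fix$ID[i]) | fix$ID[i] == ".", NA_character_, fix$ID[i]),
      genotypes = tibble(sample = samples, a1 = codes$a1, a2 = codes$a2)
    )
    ad <- if (!is.null(ad_m)) strsplit(ad_m[i, , drop = TRUE], ",", fixed = TRUE) else NULL
    purrr::imap(split_multiallelic(record), function(piece, j) {
      ref_reads <- alt_reads <- rep(NA_integer_, length(samples))
      if (!is.null(ad)) {
        ref_reads <- purrr::map_int(ad, function(x) {
          if (length(x) < 1 || is.na(x[1]) || x[1] == ".") NA_integer_ else as.integer(x[1])
        })
        alt_reads <- purrr::map_int(ad, function(x) {
          if (length(x) < j + 1 || is.na(x[j + 1]) || x[j + 1] == ".") NA_integer_ else as.integer(x[j + 1])
        })
      }
      tibble(
        sample = samples,
        contig = piece$site$contig, position = piece$site$position,
        ref = piece$site$ref, alt = piece$site$alt, rsid = piece$site$rsid,
        gt_a1 = piece$calls$gt_a1, gt_a2 = piece$calls$gt_a2,
        ref_reads = ref_reads, alt_reads = alt_reads,
        depth = if (!is.null(dp_m)) as.integer(dp_m[i, , drop = TRUE]) else NA_integer_,
        gq = if (!is.null(gq_m)) as.numeric(gq_m[i, , drop = TRUE]) else NA_real_,
        tranche = tranches[i]
      )
    }) |> bind_rows()
  }) |> bind_rows()

  # evidence is undefined for genotypes the platform did not emit
  no_call <- is.na(rows$gt_a1)
  rows$ref_reads[no_call] <- NA_integer_
  rows$alt_reads[no_call] <- NA_integer_
  rows$depth[no_call] <- NA_integer_
  rows$gq[no_call] <- NA_real_
  callset(rows, platform)
}
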