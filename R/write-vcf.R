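# Plain-text VCF 4.2 emission for simulated callsets.

tranche_to_filter <- c(
  PASS_99 = "PASS",
  TRANCHE_99_999 = "VQSRTrancheSNP99.00to99.90",
  ABOVE_999 = "VQSRTrancheSNP99.90to100.00",
  NOT_APPLICABLE = "."
)

#' Write a callset as a multi-sample VCF 4.2 file
#'
#' Emits one record per site with FORMAT `GT:AD:DP:GQ`; tranches map back to
#' FILTER strings with the same dialect [read_vcf_callset()] parses
#' (`PASS`, `VQSRTrancheSNP99.00to99.90`, ...). Samples without a call at a
#' site, and no-calls, are written as `./.` with missing evidence. Calls
#' carrying `"other"` alleles cannot be represented in a biallelic record
#' and raise an error.
#'
#' @param cs A [callset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_callset <- function(cs, path) {
  calls <- as_tibble(cs)
  if (any(calls$gt_a1 == "other" | calls$gt_a2 == "other", na.rm = TRUE)) {
    abort("Cannot write 'other' alleles into a biallelic VCF record.")
  }
  samples <- sort(unique(calls$sample))
  sites <- sites_of(calls) |> arrange(.data$contig, .data$position)
  calls$.site <- site_key(calls)

  header <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"Below the 99% truth-sensitivity threshold\">",
    "##FILTER=<ID=VQSRTrancheSNP99.00to99.90,Description=\"Truth-sensitivity tranche 99% to 99.9%\">",
    "##FILTER=<ID=VQSRTrancheSNP99.90to100.00,Description=\"Truth-sensitivity tranche above 99.9%\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  code <- function(a) ifelse(a == "alt", "1", "0")
  records <- purrr::map_chr(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    rows <- calls[calls$.site == site_key(s), ]
    rows <- rows[match(samples, rows$sample), ]
    gt <- ifelse(is.na(rows$gt_a1) | is.na(rows$sample), "./.",
                 paste0(code(rows$gt_a1), "/", code(rows$gt_a2)))
    # unordered genotypes: emit the conventional low/high allele order
    gt[gt == "1/0"] <- "0/1"
    ad <- ifelse(is.na(rows$ref_reads) | is.na(rows$alt_reads), ".",
                 paste0(rows$ref_reads, ",", rows$alt_reads))
    dp <- ifelse(is.na(rows$depth), ".", as.character(rows$depth))
    gq <- ifelse(is.na(rows$gq), ".", as.character(round(rows$gq)))
    tranche <- rows$tranche[!is.na(rows$tranche)][1]
    filt <- unname(tranche_to_filter[ifelse(is.na(tranche),
                                            "NOT_APPLICABLE", tranche)])
    paste(c(s$contig, s$position, ifelse(is.na(s$rsid), ".", s$rsid),
            s$ref, s$alt, ".", filt, ".", "GT:AD:DP:GQ",
            paste(gt, ad, dp, gq, sep = ":")), collapse = "\t")
  })
  writeLines(c(header, records), path)
  invisible(path)
}
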