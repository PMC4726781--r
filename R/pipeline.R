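# Orchestrators behind the command-line subcommands: read -> match ->
# filter -> classify -> summarise -> report, with a run manifest.

write_manifest <- function(out_dir, inputs, extra = list()) {
  manifest <- c(
    list(
      package = "pgxconcord",
      version = as.character(utils::packageVersion("pgxconcord")),
      inputs = inputs
    ),
    extra
  )
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  invisible(manifest)
}

#' Run the full cross-platform comparison
#'
#' Reads the test VCF and the truth and/or panel callsets, matches sites,
#' classifies every test call under both tranche cuts, summarises, and
#' writes the per-call report, the two-column summary, the discordant-call
#' list, and (when an adjudication table is given) the attribution report,
#' plus a run manifest. Progress counts are logged to standard error; data
#' files never interleave with logs.
#'
#' @param test Path to the test (exome) VCF.
#' @param truth Optional path to the truth VCF (amplicon platform).
#' @param panel Optional path to a panel TSV; at least one of `truth` and
#'   `panel` is required.
#' @param adjudication Optional path to a Sanger adjudication TSV.
#' @param thresholds A [filter_thresholds()] object.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of `stratified_report` objects (one per
#'   comparison run) and any `adjudication_result`s.
#' @export
run_compare <- function(test, truth = NULL, panel = NULL,
                        adjudication = NULL,
                        thresholds = filter_thresholds(),
                        out_dir = ".") {
  if (is.null(truth) && is.null(panel)) {
    abort("run_compare needs at least one of `truth` or `panel`.")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[compare] ", ...)

  test_cs <- read_vcf_callset(test, platform = "TEST_WES")
  log_msg("test callset: ", nrow(test_cs), " calls at ",
          nrow(sites_of(test_cs)), " sites")
  adj <- if (!is.null(adjudication)) read_adjudication_table(adjudication)

  results <- list()
  comparisons <- list()
  if (!is.null(truth)) {
    comparisons$truth <- read_vcf_callset(truth, platform = "TRUTH_AMPLICON")
  }
  if (!is.null(panel)) {
    comparisons$panel <- read_panel_table(panel)
  }
  for (nm in names(comparisons)) {
    report <- build_stratified_report(test_cs, comparisons[[nm]], thresholds)
    log_msg(nm, " comparison: ", report$relaxed$n_total_calls,
            " calls in universe, ", report$relaxed$n_evaluated,
            " evaluated (relaxed), ", report$relaxed$n_discordant,
            " discordant")
    write_call_report(report$calls, file.path(out_dir, paste0(nm, "_calls.tsv")))
    write_summary(report, file.path(out_dir, paste0(nm, "_summary.tsv")))
    discordant <- filter(report$calls,
                         .data$class_relaxed %in% discordant_classes)
    readr::write_tsv(discordant,
                     file.path(out_dir, paste0(nm, "_discordant.tsv")),
                     na = "")
    results[[nm]] <- report
    if (!is.null(adj)) {
      res <- adjudicate(report$calls, adj)
      write_adjudication_report(
        res, file.path(out_dir, paste0(nm, "_adjudication.tsv")))
      results[[paste0(nm, "_adjudication")]] <- res
    }
  }
  write_manifest(out_dir,
                 inputs = list(test = test, truth = truth, panel = panel,
                               adjudication = adjudication),
                 extra = list(thresholds = unclass(thresholds)))
  invisible(results)
}

#' Run the off-target distance analysis
#'
#' Annotates the sites of a callset (or a site table) with distance to the
#' nearest capture target, writes the annotation and the beyond-padding
#' report, and, when depths are available, the coverage-by-distance
#' summary.
#'
#' @param test Path to a VCF whose sites are annotated.
#' @param targets Path to the capture-target BED file.
#' @param padding Padding radius in bases (default 100).
#' @param low_coverage_threshold Aggregate-depth flag threshold
#'   (default 150).
#' @param out_dir Output directory.
#' @return Invisibly, a list with `annotation` and `coverage`.
#' @export
run_offtarget <- function(test, targets, padding = 100,
                          low_coverage_threshold = 150, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cs <- read_vcf_callset(test, platform = "TEST_WES")
  tg <- read_target_bed(targets)
  depth_by_site <- as_tibble(cs) |>
    group_by(.data$contig, .data$position, .data$ref, .data$alt,
             .data$rsid, .data$gene) |>
    summarise(aggregate_depth = sum(.data$depth, na.rm = TRUE),
              .groups = "drop")
  ann <- classify_off_target(depth_by_site, tg, padding = padding)
  cov <- coverage_by_distance(
    ann, low_coverage_threshold = low_coverage_threshold)
  write_offtarget_report(ann, file.path(out_dir, "offtarget_annotation.tsv"))
  readr::write_tsv(offtarget_report(ann),
                   file.path(out_dir, "offtarget_beyond_padding.tsv"), na = "")
  readr::write_tsv(as_tibble(cov),
                   file.path(out_dir, "coverage_by_distance.tsv"), na = "")
  write_manifest(out_dir, inputs = list(test = test, targets = targets),
                 extra = list(padding = padding,
                              low_coverage_threshold = low_coverage_threshold))
  invisible(list(annotation = ann, coverage = cov))
}

#' Run the synthetic-data generator
#'
#' Generates truth, test and panel callsets plus capture targets under a
#' seeded configuration and writes them as a test VCF, truth VCF, panel
#' TSV, targets BED, and the injected-error ledger TSV (the hidden ground
#' truth for testing recovery), plus a run manifest recording the seed.
#'
#' @param config A [simulation_config()], or a path to a YAML file of its
#'   arguments.
#' @param seed Optional integer overriding the config seed.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the three callsets and the targets.
#' @export
run_simulate <- function(config = simulation_config(), seed = NULL,
                         out_dir = ".") {
  if (is.character(config)) config <- read_simulation_config_yaml(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(config)
  test <- simulate_test_callset(truth, config)
  panel <- simulate_panel_callset(truth, config)
  targets <- simulate_targets(attr(truth, "sim_sites"), config)
  write_vcf_callset(test, file.path(out_dir, "test.vcf"))
  write_vcf_callset(truth, file.path(out_dir, "truth.vcf"))
  write_panel_table(panel, file.path(out_dir, "panel.tsv"))
  write_target_bed(targets, file.path(out_dir, "targets.bed"))
  ledger <- bind_rows(
    mutate(attr(test, "injected_errors"), platform = "TEST_WES"),
    mutate(attr(panel, "injected_errors"), platform = "PANEL")
  )
  readr::write_tsv(ledger, file.path(out_dir, "injected_errors.tsv"), na = "")
  write_manifest(out_dir, inputs = list(),
                 extra = list(seed = config$seed,
                              config = unclass(config)))
  invisible(list(truth = truth, test = test, panel = panel,
                 targets = targets))
}
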