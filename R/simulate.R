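# Seeded synthetic multi-platform callset generator: Hardy-Weinberg truth
# genotypes, read-resampled exome observations with tranche-dependent
# injected error, and a panel profile with call-rate noise.

#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a 36-sample cohort
#' typed at 43 pharmacogene-like biallelic sites, with 27/43 of sites below
#' the 99% truth-sensitivity threshold and 16/43 inside the 99-99.9%
#' tranche, exome-like overdispersed coverage, deep amplicon truth data
#' with a small missing fraction, and a panel whose per-call call rates
#' cluster in the mid-90s. Per-call genotype corruption is
#' tranche-dependent: pass-filter calls are corrupted rarely, tranche calls
#' at the much higher rate the quality stratification is designed to
#' expose.
#'
#' @param n_samples Number of diploid samples (default 36).
#' @param n_sites Number of biallelic sites (default 43).
#' @param allele_freqs Per-site alternate-allele frequencies in `[0, 1]`
#'   (recycled), or `NULL` to draw each uniformly from 0.05-0.5.
#' @param mean_depth Expected test-platform reads per call (default 40).
#' @param depth_dispersion Negative-binomial size parameter for test depth
#'   (default 8; smaller = more overdispersed).
#' @param base_error Per-read miscall probability (default 0.01).
#' @param tranche_fractions Named proportions of sites assigned to
#'   `PASS_99`, `TRANCHE_99_999`, `ABOVE_999`; must sum to 1. Sites are
#'   apportioned by largest remainder, so the split is exact.
#' @param error_rate_pass,error_rate_tranche Per-call genotype-corruption
#'   probabilities for pass-filter and tranche sites (defaults 0.004 and
#'   0.26, the discordance contrast observed in a 36-sample exome
#'   validation). `ABOVE_999` sites use `error_rate_tranche`.
#' @param missing_truth_rate Probability a truth call is absent or
#'   under-depth (default 0.07).
#' @param truth_mean_depth Mean amplicon depth for present truth calls
#'   (default 250).
#' @param panel_call_rate_params List with `mean` and `sd` of the Gaussian
#'   call-rate draw, clamped to `[0, 100]` (default mean 95, sd 4).
#' @param panel_error_rate Panel genotype-corruption probability
#'   (default 0.01).
#' @param panel_site_fraction Fraction of truth sites also assayed by the
#'   panel (default 1).
#' @param n_panel_only_sites Extra sites assayed only by the panel
#'   (default 0); useful for exercising site matching.
#' @param target_fraction Fraction of sites covered by a simulated capture
#'   target interval (default 0.8).
#' @param seed Integer seed; all draws derive from it in a fixed stage
#'   order (truth sites and genotypes, truth depths/missingness, test
#'   tranches/depths/reads/corruption, panel subset/corruption/call rates,
#'   targets), so identical seed and config give byte-identical callsets.
#' @return A list with class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 36, n_sites = 43,
                              allele_freqs = NULL,
                              mean_depth = 40, depth_dispersion = 8,
                              base_error = 0.01,
                              tranche_fractions = c(PASS_99 = 27 / 43,
                                                    TRANCHE_99_999 = 16 / 43,
                                                    ABOVE_999 = 0),
                              error_rate_pass = 0.004,
                              error_rate_tranche = 0.26,
                              missing_truth_rate = 0.07,
                              truth_mean_depth = 250,
                              panel_call_rate_params = list(mean = 95, sd = 4),
                              panel_error_rate = 0.01,
                              panel_site_fraction = 1,
                              n_panel_only_sites = 0,
                              target_fraction = 0.8,
                              seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_sites = as.integer(n_sites),
    allele_freqs = allele_freqs, mean_depth = mean_depth,
    depth_dispersion = depth_dispersion, base_error = base_error,
    tranche_fractions = tranche_fractions,
    error_rate_pass = error_rate_pass,
    error_rate_tranche = error_rate_tranche,
    missing_truth_rate = missing_truth_rate,
    truth_mean_depth = truth_mean_depth,
    panel_call_rate_params = panel_call_rate_params,
    panel_error_rate = panel_error_rate,
    panel_site_fraction = panel_site_fraction,
    n_panel_only_sites = as.integer(n_panel_only_sites),
    target_fraction = target_fraction,
    seed = as.integer(seed)
  )
  bad <- character()
  probs <- c("base_error", "error_rate_pass", "error_rate_tranche",
             "missing_truth_rate", "panel_error_rate",
             "panel_site_fraction", "target_fraction")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) bad <- c(bad, p)
  }
  if (cfg$n_samples < 1) bad <- c(bad, "n_samples")
  if (cfg$n_sites < 1) bad <- c(bad, "n_sites")
  if (abs(sum(cfg$tranche_fractions) - 1) > 1e-8) bad <- c(bad, "tranche_fractions")
  if (!is.null(cfg$allele_freqs) &&
      (any(cfg$allele_freqs < 0) || any(cfg$allele_freqs > 1))) {
    bad <- c(bad, "allele_freqs")
  }
  if (cfg$mean_depth <= 0 || cfg$depth_dispersion <= 0) bad <- c(bad, "mean_depth/depth_dispersion")
  if (length(bad)) {
    abort(paste0("Invalid simulation config field(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  structure(cfg, class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' @param path YAML file whose keys mirror [simulation_config()] arguments.
#' @return A `simulation_config`.
#' @export
read_simulation_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(simulation_config))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    abort(paste0("Unknown simulation config keys: ", paste(bad, collapse = ", ")))
  }
  if (!is.null(cfg$tranche_fractions)) {
    cfg$tranche_fractions <- unlist(cfg$tranche_fractions)
  }
  do.call(simulation_config, cfg)
}

dosage_to_gt <- function(dosage) {
  list(
    a1 = ifelse(dosage == 2, "alt", "ref"),
    a2 = ifelse(dosage >= 1, "alt", "ref")
  )
}

sim_sites <- function(config) {
  n <- config$n_sites + config$n_panel_only_sites
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- purrr::map_chr(ref, function(r) sample(setdiff(bases, r), 1))
  tibble(
    contig = "sim1",
    position = as.integer(1000 + (seq_len(n) - 1) * 700 +
                            sample.int(300, n, replace = TRUE)),
    ref = ref, alt = alt,
    rsid = sprintf("rssim%04d", seq_len(n)),
    gene = ifelse(seq_len(n) %% 2 == 1, "GENEA", "GENEB"),
    star_allele = NA_character_
  )
}

#' Generate a Hardy-Weinberg truth callset
#'
#' Draws per-site alternate-allele frequencies (unless supplied), then for
#' each sample draws the alt dosage as Binomial(2, q) — the Hardy-Weinberg
#' genotype proportions p^2 / 2pq / q^2. Truth depths are drawn deep (at
#' least 10-fold) except for a `missing_truth_rate` fraction of calls that
#' are either dropped entirely or assigned sub-threshold depth, half each
#' in expectation.
#'
#' @param config A [simulation_config()].
#' @return A `TRUTH_AMPLICON` [callset()]. The full latent genotype grid
#'   (including masked calls) is attached as attribute `"latent"`; the site
#'   roster (including panel-only sites) as `"sim_sites"`; the realised
#'   allele frequencies as `"allele_freqs"`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  sites <- sim_sites(config)
  truth_sites <- sites[seq_len(config$n_sites), ]
  q <- config$allele_freqs %||% runif(config$n_sites, 0.05, 0.5)
  q <- rep_len(q, config$n_sites)
  samples <- sprintf("S%03d", seq_len(config$n_samples))

  grid <- tidyr::expand_grid(site_idx = seq_len(config$n_sites),
                             sample = samples)
  grid$dosage <- rbinom(nrow(grid), 2, q[grid$site_idx])
  latent <- bind_rows(purrr::map(seq_len(config$n_sites), function(i) {
    g <- grid[grid$site_idx == i, ]
    tibble(sample = g$sample, truth_sites[rep(i, nrow(g)), ], dosage = g$dosage)
  }))

  depth <- config$truth_dp_floor %||% 10L
  latent$truth_depth <- depth + rnbinom(
    nrow(latent), mu = max(config$truth_mean_depth - depth, 1), size = 10
  )
  mask <- runif(nrow(latent)) < config$missing_truth_rate
  drop_entirely <- mask & runif(nrow(latent)) < 0.5
  latent$truth_depth[mask & !drop_entirely] <-
    sample.int(depth, sum(mask & !drop_entirely), replace = TRUE) - 1L

  observed <- latent[!drop_entirely, ]
  gt <- dosage_to_gt(observed$dosage)
  alt_reads <- ifelse(observed$dosage == 2, observed$truth_depth,
                      ifelse(observed$dosage == 1,
                             rbinom(nrow(observed), observed$truth_depth, 0.5),
                             0L))
  cs <- callset(tibble(
    sample = observed$sample, contig = observed$contig,
    position = observed$position, ref = observed$ref, alt = observed$alt,
    rsid = observed$rsid, gene = observed$gene,
    gt_a1 = gt$a1, gt_a2 = gt$a2,
    ref_reads = as.integer(observed$truth_depth - alt_reads),
    alt_reads = as.integer(alt_reads),
    depth = as.integer(observed$truth_depth)
  ), "TRUTH_AMPLICON")
  attr(cs, "latent") <- latent
  attr(cs, "sim_sites") <- sites
  attr(cs, "allele_freqs") <- q
  attr(cs, "config") <- config
  cs
}

#' Diploid genotype call and quality from read counts
#'
#' Standard flat-prior diploid binomial genotype likelihood: given
#' `alt_reads` alternate reads out of `ref_reads + alt_reads` total, each
#' genotype class emits an alternate read with probability `base_error`
#' (hom-ref), 1/2 (het) or `1 - base_error` (hom-alt). The call is the
#' maximum-likelihood class and GQ is the Phred-scaled posterior error of
#' that call, rounded and capped at 99 — consistent with GQ's definition as
#' the Phred-scaled confidence that the genotype assignment is correct.
#' Zero total reads yield a no-call with absent GQ.
#'
#' @param ref_reads,alt_reads Non-negative integer vectors.
#' @param base_error Per-read miscall probability in (0, 0.5); 0 is allowed
#'   and makes hom classes emit deterministically.
#' @return A tibble with `call` (`"hom_ref"`, `"het"`, `"hom_alt"` or `NA`)
#'   and `gq`.
#' @export
genotype_quality <- function(ref_reads, alt_reads, base_error = 0.01) {
  stopifnot(all(ref_reads >= 0, na.rm = TRUE), all(alt_reads >= 0, na.rm = TRUE))
  p_alt <- c(hom_ref = base_error, het = 0.5, hom_alt = 1 - base_error)
  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))
  n <- length(ref_reads)
  ll <- sapply(p_alt, function(p) {
    xlogy(alt_reads, p) + xlogy(ref_reads, 1 - p)
  })
  ll <- matrix(ll, nrow = n)
  empty <- (ref_reads + alt_reads) == 0 | is.na(ref_reads + alt_reads)
  best <- max.col(ll, ties.method = "first")
  post <- exp(ll - apply(ll, 1, max))
  post <- post / rowSums(post)
  p_err <- 1 - post[cbind(seq_len(n), best)]
  gq <- pmin(round(-10 * log10(pmax(p_err, 1e-10))), 99)
  tibble(
    call = ifelse(empty, NA_character_, names(p_alt)[best]),
    gq = ifelse(empty, NA_real_, as.numeric(gq))
  )
}

apportion_tranches <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  rep(names(fractions), times = counts)
}

corrupt_class <- function(call, u) {
  classes <- c("hom_ref", "het", "hom_alt")
  purrr::map2_chr(call, u, function(cl, uu) {
    others <- setdiff(classes, cl)
    others[1 + (uu >= 0.5)]
  })
}

class_to_gt <- function(call) {
  list(
    a1 = dplyr::case_when(call == "hom_alt" ~ "alt",
                          is.na(call) ~ NA_character_, TRUE ~ "ref"),
    a2 = dplyr::case_when(call %in% c("het", "hom_alt") ~ "alt",
                          is.na(call) ~ NA_character_, TRUE ~ "ref")
  )
}

#' Simulate a test (exome-like) callset from truth
#'
#' Per latent truth call: a read depth is drawn from a negative binomial
#' with the configured mean and dispersion; alternate-read counts are drawn
#' binomially from the truth dosage's emission probability; the genotype
#' and GQ come from [genotype_quality()]. Each site is assigned a VQSR
#' tranche by the configured fractions (largest-remainder apportionment,
#' seeded shuffle), and each emitted genotype is corrupted with the
#' tranche's error rate to a uniformly chosen different class. Every
#' injected corruption is recorded in a ledger attached as attribute
#' `"injected_errors"`.
#'
#' @param truth Output of [generate_truth()].
#' @param config The same [simulation_config()].
#' @return A `TEST_WES` [callset()] with attribute `"injected_errors"`.
#' @export
simulate_test_callset <- function(truth, config) {
  latent <- attr(truth, "latent")
  if (is.null(latent)) abort("truth must come from generate_truth().")
  set.seed(config$seed + 1L)

  site_tranche <- sample(apportion_tranches(config$tranche_fractions,
                                            config$n_sites))
  names(site_tranche) <- unique(latent$rsid)
  err_rate <- c(PASS_99 = config$error_rate_pass,
                TRANCHE_99_999 = config$error_rate_tranche,
                ABOVE_999 = config$error_rate_tranche)

  n <- nrow(latent)
  depth <- rnbinom(n, mu = config$mean_depth, size = config$depth_dispersion)
  p_emit <- c(config$base_error, 0.5, 1 - config$base_error)[latent$dosage + 1]
  alt_reads <- rbinom(n, depth, p_emit)
  ref_reads <- depth - alt_reads
  gtq <- genotype_quality(ref_reads, alt_reads, config$base_error)

  tranche <- unname(site_tranche[latent$rsid])
  corrupt <- runif(n) < err_rate[tranche] & !is.na(gtq$call)
  u <- runif(n)  # drawn for every call to keep the stream length fixed
  final_call <- gtq$call
  final_call[corrupt] <- corrupt_class(gtq$call[corrupt], u[corrupt])

  gt <- class_to_gt(final_call)
  cs <- callset(tibble(
    sample = latent$sample, contig = latent$contig,
    position = latent$position, ref = latent$ref, alt = latent$alt,
    rsid = latent$rsid, gene = latent$gene,
    gt_a1 = gt$a1, gt_a2 = gt$a2,
    ref_reads = as.integer(ifelse(depth == 0, NA, ref_reads)),
    alt_reads = as.integer(ifelse(depth == 0, NA, alt_reads)),
    depth = as.integer(ifelse(depth == 0, NA, depth)),
    gq = gtq$gq,
    tranche = tranche
  ), "TEST_WES")
  attr(cs, "injected_errors") <- tibble(
    sample = latent$sample[corrupt], rsid = latent$rsid[corrupt],
    contig = latent$contig[corrupt], position = latent$position[corrupt],
    ref = latent$ref[corrupt], alt = latent$alt[corrupt],
    tranche = tranche[corrupt],
    original = gtq$call[corrupt], corrupted = final_call[corrupt]
  )
  attr(cs, "site_tranche") <- site_tranche
  cs
}

#' Simulate a panel callset from truth
#'
#' Genotypes are copied from the latent truth at a configurable subset of
#' sites, corrupted at `panel_error_rate` to a uniformly chosen different
#' class; per-call call rates are Gaussian draws clamped to `[0, 100]`.
#' Extra panel-only sites (hom-ref everywhere) can be added to exercise
#' site matching. Injected corruptions are attached as
#' `"injected_errors"`.
#'
#' @inheritParams simulate_test_callset
#' @return A `PANEL` [callset()].
#' @export
simulate_panel_callset <- function(truth, config) {
  latent <- attr(truth, "latent")
  sites <- attr(truth, "sim_sites")
  if (is.null(latent)) abort("truth must come from generate_truth().")
  set.seed(config$seed + 2L)

  n_on_panel <- max(1L, floor(config$panel_site_fraction * config$n_sites))
  panel_rsids <- sort(sample(unique(latent$rsid), n_on_panel))
  sub <- latent[latent$rsid %in% panel_rsids, ]
  truth_class <- c("hom_ref", "het", "hom_alt")[sub$dosage + 1]
  corrupt <- runif(nrow(sub)) < config$panel_error_rate
  u <- runif(nrow(sub))
  final_call <- truth_class
  final_call[corrupt] <- corrupt_class(truth_class[corrupt], u[corrupt])
  call_rate <- pmin(pmax(rnorm(nrow(sub),
                               config$panel_call_rate_params$mean,
                               config$panel_call_rate_params$sd), 0), 100)
  gt <- class_to_gt(final_call)
  calls <- tibble(
    sample = sub$sample, contig = sub$contig, position = sub$position,
    ref = sub$ref, alt = sub$alt, rsid = sub$rsid, gene = sub$gene,
    gt_a1 = gt$a1, gt_a2 = gt$a2, call_rate = call_rate
  )
  if (config$n_panel_only_sites > 0) {
    extra <- sites[config$n_sites + seq_len(config$n_panel_only_sites), ]
    samples <- unique(latent$sample)
    extra_calls <- tidyr::expand_grid(sample = samples,
                                      extra[, c("contig", "position", "ref",
                                                "alt", "rsid", "gene")]) |>
      mutate(gt_a1 = "ref", gt_a2 = "ref",
             call_rate = pmin(pmax(
               rnorm(dplyr::n(), config$panel_call_rate_params$mean,
                     config$panel_call_rate_params$sd), 0), 100))
    calls <- bind_rows(calls, extra_calls)
  }
  cs <- callset(calls, "PANEL")
  attr(cs, "injected_errors") <- tibble(
    sample = sub$sample[corrupt], rsid = sub$rsid[corrupt],
    original = truth_class[corrupt], corrupted = final_call[corrupt]
  )
  cs
}

#' Simulate capture-target intervals for a site roster
#'
#' A seeded fraction of sites receive a covering interval (50 bases
#' upstream to 100 downstream); the remainder are left off-target at
#' whatever distance the merged intervals imply.
#'
#' @param sites Site tibble (e.g. `attr(truth, "sim_sites")`).
#' @param config A [simulation_config()].
#' @return A `target_intervals` tibble.
#' @export
simulate_targets <- function(sites, config) {
  set.seed(config$seed + 3L)
  covered <- runif(nrow(sites)) < config$target_fraction
  iv <- tibble(
    contig = sites$contig[covered],
    start = pmax(sites$position[covered] - 50L, 1L),
    end = sites$position[covered] + 100L
  )
  if (nrow(iv) == 0) {
    out <- tibble(contig = character(), start = integer(), end = integer())
    return(structure(out, class = c("target_intervals", class(out))))
  }
  merged <- iv |>
    group_by(.data$contig) |>
    dplyr::reframe({
      red <- IRanges::reduce(IRanges::IRanges(start = .data$start, end = .data$end))
      tibble(start = IRanges::start(red), end = IRanges::end(red))
    }) |>
    arrange(.data$contig, .data$start)
  structure(as_tibble(merged),
            class = c("target_intervals", class(merged)))
}
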