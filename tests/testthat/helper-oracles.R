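# Independent oracles used to freeze expected values. Each is written
# against the definition, not the implementation it checks.

# Brute-force allele-trim oracle: enumerate every (prefix, suffix) trim
# that keeps both alleles non-empty and preserves the shared flanks, then
# apply the maximal suffix trim followed by the maximal prefix trim.
oracle_normalize <- function(position, ref, alt) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  best <- c(p = 0L, s = 0L)
  for (s in 0:(min(length(r), length(a)) - 1L)) {
    if (s > 0 && !identical(utils::tail(r, s), utils::tail(a, s))) break
    for (p in 0:(min(length(r), length(a)) - s - 1L)) {
      if (p > 0 && !identical(r[seq_len(p)], a[seq_len(p)])) break
      if (s > best["s"] || (s == best["s"] && p > best["p"])) {
        best <- c(p = p, s = s)
      }
    }
  }
  keep_r <- r[seq(best["p"] + 1L, length(r) - best["s"])]
  keep_a <- a[seq(best["p"] + 1L, length(a) - best["s"])]
  list(position = position + best[["p"]],
       ref = paste(keep_r, collapse = ""),
       alt = paste(keep_a, collapse = ""))
}

# Exhaustive genotype-comparison truth table for the 3x3 pure ref/alt
# genotype space, written out by hand from the definitions.
oracle_compare_table <- tibble::tribble(
  ~test,      ~truth,     ~class,
  "hom_ref",  "hom_ref",  "CONCORDANT",
  "hom_ref",  "het",      "FALSE_NEGATIVE",
  "hom_ref",  "hom_alt",  "FALSE_NEGATIVE",
  "het",      "hom_ref",  "FALSE_POSITIVE",
  "het",      "het",      "CONCORDANT",
  "het",      "hom_alt",  "FALSE_NEGATIVE",
  "hom_alt",  "hom_ref",  "FALSE_POSITIVE",
  "hom_alt",  "het",      "FALSE_POSITIVE",
  "hom_alt",  "hom_alt",  "CONCORDANT"
)

gt_of_class <- function(class) {
  switch(class,
    hom_ref = c("ref", "ref"),
    het = c("ref", "alt"),
    hom_alt = c("alt", "alt")
  )
}

# Per-base brute-force distance scan over an explicit base grid.
oracle_distance <- function(position, starts, ends) {
  if (length(starts) == 0) return(Inf)
  bases <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
  min(abs(position - bases))
}

# Sort-based median, independent of stats::median's interpolation path.
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Flat-prior diploid binomial genotype likelihood, coded independently
# (direct probability-space enumeration, no log-space shortcuts).
oracle_genotype_quality <- function(ref_reads, alt_reads, eps = 0.01) {
  p <- c(hom_ref = eps, het = 0.5, hom_alt = 1 - eps)
  lik <- sapply(p, function(pp) pp^alt_reads * (1 - pp)^ref_reads)
  post <- lik / sum(lik)
  best <- which.max(lik)
  list(call = names(p)[best],
       gq = min(round(-10 * log10(max(1 - post[best], 1e-10))), 99))
}
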