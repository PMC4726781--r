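Package: pgxconcord
Title: Cross-Platform Genotype Concordance Benchmarking for Pharmacogenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quality-stratified comparison of an exome-sequencing callset
    against amplicon-sequencing truth data and a multiplexed genotyping-panel
    profile. Implements evaluability filtering on per-genotype read depth and
    genotype quality, VQSR truth-sensitivity tranche stratification,
    exhaustive per-call classification (concordant, false positive, false
    negative, mixed), Sanger-style adjudication of discordant calls,
    distance-to-capture-target annotation with coverage-by-distance
    summaries, and a seeded synthetic multi-platform callset generator with
    Hardy-Weinberg truth genotypes and tranche-dependent injected error so
    the whole pipeline is testable without external data. All user-facing
    functions take and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    vcfR,
    IRanges,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
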