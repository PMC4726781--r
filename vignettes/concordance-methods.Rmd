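---
title: "Quality-stratified genotype concordance: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-stratified genotype concordance: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxconcord)
```

## The problem

Exome sequencing of pharmacogenes is attractive — one assay yields both
diagnostic and pharmacogenomic information — but its genotype calls in
loci like *CYP2D6* (shadowed by the *CYP2D7/8* pseudogenes) need
validation against orthogonal platforms before anyone doses a drug on
them. `pgxconcord` formalises that validation as a reproducible pipeline:
an exome ("test") callset is compared per genotype call against deep
amplicon resequencing ("truth") and/or a multiplexed genotyping panel,
with disagreements optionally adjudicated by Sanger sequencing.

The package treats a callset as a tibble with one row per
(sample, site, platform) call. Sites are biallelic after multiallelic
splitting; genotypes are unordered, unphased and diploid. Haploid or
higher-ploidy records are rejected rather than coerced: every locus this
pipeline targets is autosomal diploid, and silent coercion would mask
upstream errors.

## Site identity

Two platforms only compare correctly if they spell variants identically.
`normalize_site()` trims the shared allele suffix, then the shared prefix
(keeping one leading base for indels, advancing the position per trimmed
prefix base), which makes VCF-style and panel-style spellings of the same
variant canonical and the operation idempotent. We deliberately do **not**
left-align indels against a reference genome: that keeps the package free
of FASTA downloads, and the platforms being compared report variants at
identical declared coordinates. The cost, documented as a limitation, is
that an indel reported at two different anchor points will not match.

Matching uses the (contig, position, ref, alt) key first; a record that
carries only an rsID (as panel exports often do) falls back to rsID
matching, and every fallback is reported. One rsID mapping to two
different coordinate keys is an error, not a silent choice.

## Evaluability rules and their boundaries

Four pure predicates implement the comparison's quality gates, with the
inequality directions kept literal and unit-tested at the boundary:

| rule | predicate | boundary |
|---|---|---|
| test call evaluable | DP ≥ 4 and GQ ≥ 10 | DP 4, GQ 10 pass; DP 3 fails; absent evidence fails |
| tranche cut | tranche ∈ cut | strict = {below 99%}; relaxed adds the 99–99.9% tranche |
| truth confident | amplicon depth ≥ 10 | depth 10 passes, 9 fails |
| panel confident | call rate > 85% | 85.0 fails (strict inequality) |

All four thresholds are configurable (`filter_thresholds()`, YAML, or CLI
flags); the defaults are the validated exome-profiling values above.

## The classification cascade

Each test call at a shared site gets exactly one class, decided in order:
tranche exclusion first (stratification precedes everything, so a
low-quality call outside the cut lands in the tranche bucket, not the
quality bucket), then platform no-calls, then evaluability, then
missing/unconfident truth (with the sub-reason — absent record, truth
no-call, low depth or low call rate — retained per call), then genotype
comparison. One ordering choice deserves a note: no-calls are recognised
*before* the DP/GQ test. A genotype the platform never emitted carries no
GQ, so testing evaluability first would absorb every no-call into the
low-quality bucket and the no-call count — reported separately in the
stratified summary — could never be non-zero.

Genotype comparison is by alternate-allele copy counting on unordered
multisets, so `0/1` and `1/0` are equal. A test call introducing an alt
copy the truth lacks is a false positive; missing one the truth has is a
false negative — which deliberately includes the het-called-where-truth-
is-hom-alt case, since one alternate copy went undetected. Any
involvement of an allele foreign to the biallelic site (from multiallelic
projection) is mixed-discordant rather than silently reference: collapsing
a third allele onto the reference class would hide true cross-allele
disagreements. The comparison is symmetric under platform exchange with
FP and FN swapping roles, and is pinned in tests against an independently
written 3×3 truth table.

The per-stratum summary asserts its own conservation identities on every
run: total = low-quality + no-calls + missing-truth + evaluated;
evaluated = concordant + discordant; discordant = FP + FN + mixed. The
concordance rate is `100 × concordant / evaluated` over **all** evaluated
calls — hom-ref concordant calls included — matching how validation
studies report their denominators; a restricted alt-carrying denominator
was considered and rejected because its published decompositions are not
recoverable unambiguously. Reported rates are formatted to two decimals
with half-up rounding (`format_rate()`), since R's round-half-to-even
would alter printed values at exact halves.

## Adjudication

Sanger adjudication never rewrites a classification. For each discordant
(sample, site) with a record, the platform whose genotype matches the
Sanger alleles is attributed as correct; both-mismatch is `BOTH_WRONG`;
records for non-discordant pairs are warned about and ignored, because an
adjudication that "confirms" an already-concordant call usually signals a
sample-tracking mistake.

## Off-target distance

Distance to the nearest capture target is measured in whole bases on
1-based closed intervals from the variant's normalized leftmost position:
0 inside an interval, `s − p` left of a target starting at `s`, `p − e`
right of one ending at `e`. (This is one more than an interval library's
"gap width" convention — the implementation is checked against a per-base
brute-force scan, not against such a library.) BED input is 0-based
half-open and converted on read; intervals are merged per contig before
any distance is computed. Indel end positions are ignored: a single
per-variant distance is what downstream reports need. Sites on contigs
with no targets at all are flagged uncapturable (`Inf`) rather than given
an arbitrary large number.

The coverage-by-distance summary bins annotated sites (default edges
0 / 1 / 51 / 101 / 201 / ∞ bases, separating on-target calls from
progressively remoter off-target ones) and reports per-bin site counts,
median and maximum aggregate depth, flagging bins whose maximum falls
below a threshold (default 150-fold summed across a 36-sample cohort —
the empirical depth floor observed beyond ~100 bases, which motivates the
default 100-base padding radius for rescuing off-target calls).

## The synthetic generator

The generator exists so every pipeline stage is testable against known
ground truth. Its defaults are the study conditions the package targets:
36 samples, 43 biallelic pharmacogene-like sites, 27/43 below the 99%
truth-sensitivity threshold and 16/43 in the 99–99.9% tranche
(apportioned by largest remainder so the split is exact), per-call
corruption probabilities 0.004 for pass-filter sites and 0.26 for tranche
sites (the observed discordance contrast), 7% missing truth, amplicon
truth depth ~250×, panel call rates ~N(95, 4) clamped to [0, 100] with 1%
panel corruption. Where the emulated study prints no value we fixed one
realistic choice once: alternate-allele frequencies uniform on
0.05–0.5 (pharmacogene variants under validation are mostly common
polymorphisms), exome depth negative-binomial with mean 40 and size 8
(overdispersed capture coverage; the low tail deliberately produces
sub-threshold DP calls), per-read miscall probability 0.01.

Truth genotypes are Hardy–Weinberg draws — alt dosage ~ Binomial(2, q) —
which tests verify by chi-square goodness of fit at large n. Test
observations re-sequence the latent truth: depth from the negative
binomial, alternate reads binomial with per-read alt probability ε, ½ or
1−ε by dosage, then a maximum-likelihood diploid genotype with a
Phred-scaled posterior-error GQ capped at 99 (`genotype_quality()`,
flat prior). This is the standard binomial likelihood model; GQ is defined
only verbally in the sources as the Phred-scaled confidence in the call,
and any monotone evidence-consistent realisation would do — this one is
exactly enumerable, and tests check it against an independent
probability-space implementation for every read-count pair up to depth 12.
Corruption then replaces the called class, with the site's
tranche-specific probability, by one of the other two classes uniformly —
chosen over "always flip to ref/alt" because it exercises both the FP and
the FN branch — and logs every event in a hidden ledger, letting tests
equate pipeline discordants with injected errors call-for-call when truth
is complete and everything is evaluable.

A single seed governs all draws in a frozen stage order (truth sites and
genotypes; truth depth and missingness; test tranches, depths, reads,
corruption; panel subset, corruption, call rates; targets), so one seed
reproduces every file byte-for-byte. One subtlety: corruption uniforms are
drawn for every call, not only corrupted ones, so the stream position of
later stages does not depend on earlier outcomes.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: pseudogene homology contamination (the
dominant real *CYP2D6* failure mode), alignment and reference bias shared
between platforms, ploidy-violating structural alleles, batch effects in
panel call rates, and any correlation of errors across samples at a site.
Recovery of injected error rates demonstrates the bookkeeping is right,
not that real exome errors behave like the injection model.

## Problem sizes and numerics

The test suite runs the full pipeline at small scale (tens of samples,
tens of sites) and the statistical checks at the sizes their power needs:
10 000 samples for the Hardy–Weinberg standard-error check, ~5 400 calls
for per-tranche error-rate recovery within three binomial standard
deviations, 1 000 randomized interval fixtures for the distance oracle.
These sizes were chosen as the smallest that make the statistical
assertions stable across seeds. Likelihood computations are done in log
space with the `0·log 0 = 0` convention so `base_error = 0` is an exact,
supported configuration; posterior errors are floored at 1e-10 before
Phred scaling, which only affects values already beyond the GQ-99 cap.

## Known limitations

No reference-genome left-alignment (above); no gVCF semantics — absent
records are "missing", not "confidently reference"; site-level
sensitivity/precision curves and callset QC metrics (Ti/Tv etc.) are out
of scope; CNVs, hybrid alleles and star-allele diplotype translation are
carried as annotations at most. The bundled worked-example fixtures pin
published summary figures; per-sample source data were never deposited,
so the full original experiment is reconstructed only at the bookkeeping
level, with genotype-level details synthetic.
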