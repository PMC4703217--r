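---
title: "Methods: cohort demography and diagnostic-site biotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort demography and diagnostic-site biotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidbiotype)
```

This vignette documents the models behind the package, the choices made
where the underlying experimental conventions are genuinely open, and
what the synthetic-data tests do and do not demonstrate about field
data.

## The cohort model

A host-transfer experiment starts a cohort of 8–10 first-stadium aphid
nymphs on an excised leaf of the test plant; the founding adults are
removed after 24 h. Daily checks record the number alive and the number
of newborn nymphs (which are counted and removed) until the cohort is
extinct. One cohort is one replicate; a treatment ("cotton to
cucumber", say) comprises 10–30 replicates.

**Age origin.** The recording convention never states whether age
starts at 0 or 1. Here age `x = 1` denotes the first daily check after
cohort initiation, i.e. roughly 24–48 h of age. This is a bookkeeping
choice: it shifts T by at most one day and leaves R₀ untouched; users
who prefer another origin can relabel the `day` column before analysis.

**The m_x denominator.** Daily offspring counts are divided by the
number alive at that day's check. Cotton-melon aphids in these
conditions are exclusively parthenogenetic females, so no sex-ratio
factor enters m_x. When the cohort is extinct, m_x is 0 by definition
rather than 0/0.

**Missing checks.** Occasional lapses in the daily routine are handled
by carrying the last observed `n_alive` forward with `m_x = 0` on the
skipped days, so every schedule has one row per calendar day. This
under-counts reproduction if nymphs produced on a skipped day were
discarded uncounted, which is the conservative direction.

From the schedule, the three parameters are

- R₀ = Σ l_x m_x (expected lifetime offspring per newborn),
- T = Σ x l_x m_x / Σ l_x m_x (fecundity-weighted mean age of
  reproduction, days),
- r_m = ln R₀ / T (per-day growth rate).

r_m here is the classical log-ratio approximation, not the implicit
Euler–Lotka root; the approximation is what the tables this package
mirrors report, and the package deliberately provides nothing else.
r_m is negative exactly when R₀ < 1 and undefined when R₀ = 0 (a
treatment where no individual ever reproduced prints as a dash and is
excluded from T and r_m means, with the exclusion count reported).

**Per-replicate vs pooled aggregation.** The default computes R₀, T,
r_m per replicate and reports mean ± sample SD, because printed SDs can
only come from replicate-level values. Published r_m means, however,
are sometimes consistent with ln(mean R₀)/mean T instead; both
conventions are plausible and the discrepancy cannot be resolved from
the printed tables alone. `replicate_parameters(pooled = TRUE)`
therefore also returns parameters of the treatment-mean schedule, and
the two modes coincide when replicates are homogeneous. We document the
ambiguity rather than resolve it.

**Display rounding.** Survival percentages, R₀ and T round to 1
decimal, r_m to 2, survey percentages to integers — all half away from
zero (`round_half_up()`), matching how such tables are typeset; base
R's banker's rounding would differ at exact halves.

## Group comparisons

Treatments are compared nonparametrically: Mann–Whitney U for pairs,
Kruskal–Wallis (tie-corrected H, χ² approximation on k − 1 df) for
three or more groups. The package delegates the distributions to
`stats::wilcox.test()` and `stats::kruskal.test()` and fixes the
protocol around them:

- the exact U distribution is used when the combined sample size is at
  most 10 and the data are tie-free; otherwise the normal approximation
  with tie and continuity corrections. Ten is small enough that full
  enumeration is instant and large enough to cover every case where the
  approximation is materially off (the suite verifies exact-vs-oracle
  equality below n = 10 and agreement within 0.02 at n = 16);
- all tests are two-sided (sidedness is never stated in the tables this
  mirrors);
- significance marks follow the convention `**` for p < 0.01, `*` for
  0.01 ≤ p < 0.05.

**Compact letter display.** The letters ("values followed by different
letters differ significantly") are produced by pairwise two-sided
Mann–Whitney tests at α = 0.05 followed by the insert-and-absorb
algorithm over groups sorted by descending mean, so the highest group
always carries "a" and letter-sharing mirrors non-significance exactly.
Pairwise p-values are uncorrected by default — the apparent practice
behind such annotations — with `correct = "bonferroni"` available; with
three groups the correction factor is 3, so the flag matters mostly for
borderline pairs.

## The diagnostic marker

The biotype assay amplifies a mitochondrial cytb–16S fragment with the
primer pair CytbF/16SR and reads five single-nucleotide sites that are
fixed differences between the biotypes: T,A,A,T,T (cotton) versus
C,G,G,C,C (cucumber). A `marker_definition` bundles the primers, the
five offsets (1-based, counted from the first base after the forward
primer), both patterns, and the mismatch tolerance; the constructor
enforces that the patterns differ at all five sites, which makes the
two calls mutually exclusive by construction.

The genomic coordinates of the real amplicon are not public, so the
packaged `default_marker()` places the five sites at arbitrary,
documented offsets (28, 41, 55, 68, 82) and the two reference fragments
in `inst/extdata/` are synthetic sequences carrying the published
patterns at those offsets — they are labelled synthetic in both
filename and FASTA headers and are not excerpts of any accession.
Analyses of real amplicons must supply a marker config with the true
offsets; every downstream function takes the marker as data, not as a
constant.

**Classification rules.**

- Forward primer found (≤ `max_primer_mismatches`, default 2,
  exact matches preferred, forward strand before reverse complement) →
  the fragment is anchored; otherwise the record is not amplifiable and
  is called `other_species`, mirroring a diagnostic PCR that fails on a
  divergent template. Two mismatches is a routine tolerance for a
  26-mer primer at high annealing temperature; a random 200-mer matches
  it nowhere, so the fallback is safe.
- All five sites match one pattern → that biotype.
- Any IUPAC ambiguity code at a diagnostic site → `ambiguous` (the
  read cannot be trusted), never a biotype and never `other_species`.
- Anything else — including mixtures of the two patterns — →
  `other_species`: a single off-pattern site is far more likely to be a
  divergent species than a within-biotype mutation at a site chosen for
  being fixed.

Sequences are normalized (uppercase, U→T) before comparison, and
classification is strand-invariant: a record and its reverse complement
always receive the same call.

## Survey tables

`summarize_survey()` groups calls by collection time, host plant, and
morph and reports each class as a percentage. `ambiguous` calls are
excluded from the denominator and counted separately — field surveys
have no such class, so this is an additive refinement that keeps the
three raw fractions summing to exactly 1. Rounded display percentages
(integer, half-up) ride alongside the raw fractions; with three classes
the rounded row sums lie within 100 ± 1, and some published rows are
not exactly reconstructible from any integer counts, which we treat as
upstream rounding artifacts rather than model them.

## The synthetic-data generators

`simulate_cohorts()` draws each individual's survival as an independent
Bernoulli chain over day-specific probabilities and offspring as
Poisson per survivor — Poisson being the simplest non-negative integer
model for daily nymph production, a modeling choice rather than an
empirical claim. The closed form `analytic_truth()` gives
E[R₀] = Σ_x (Π_{i≤x} p_i) f_x with T and r_m from the expected
schedule; per-replicate R₀ from the simulator is unbiased for this
value, which the recovery tests exploit (200 replicates, 3-SE band).

The default configuration emulates a cohort on its natal host: 10
nymphs, daily survival 0.98 for a 5-day pre-reproductive period, then
0.97 over 10 reproductive days at mean fecundity 4 nymphs per survivor
per day. Its analytic expectation — R₀ = 30.7, T ≈ 10.3 d,
r_m ≈ 0.33/d — sits at the scale reported for cotton-biotype aphids on
cotton, and the defaults were fixed from that protocol description
once, not tuned afterward. Transfer treatments that collapse are
emulated by low survival and near-zero fecundity (see the demo CSV),
producing R₀ < 1, negative r_m, and replicates with no reproduction at
all.

`simulate_marker_sequences()` builds primer-flanked amplicons with the
diagnostic pattern written at the marker offsets and i.i.d. background
substitutions elsewhere; other-species records are random sequences
with no primer site. Every second record is emitted
reverse-complemented so strand handling is always exercised.

**What passing tests show — and do not.** Perfect classification at
zero noise and exact parameter recovery demonstrate that the pipeline's
logic is correct, deterministic, and strand- and permutation-invariant.
Real data differ in ways the generators deliberately omit: sequencing
chimeras and indels, primer-site variation *within* A. gossypii,
correlated (weather-driven) mortality across a cohort, density
dependence, and day-varying individual fecundity. Passing the synthetic
suite therefore validates the arithmetic and the decision rules, not
the field adequacy of the marker or the protocol.

## Numerical and degenerate-input conventions

- Problem sizes in the test suite: 2,000 null simulations for the
  type-I error check, 200 replicates for parameter recovery, 1,000
  fragments for the classification sweep — sizes at which the binomial
  or SE bands in the assertions are decisive.
- Validation is strict and names the offending day or record:
  increasing `n_alive`, offspring after extinction, days before the
  first observation, non-IUPAC characters, and metadata/FASTA id
  mismatches all abort rather than warn.
- `survival_percent()` carries the last observation forward beyond the
  final check (the cohort is extinct or static) but refuses days before
  the first check.
- All file outputs use fixed column orders and deterministic
  formatting, so re-running a pipeline on identical inputs is
  byte-identical.
- Seeds: every generator takes an explicit integer seed; the same seed
  reproduces outputs exactly.

## Known limitations

- r_m is the ln R₀/T approximation; for schedules with long
  reproductive tails it can differ noticeably from the Euler–Lotka
  rate. Out of scope by design.
- The compact-letter procedure is uncorrected pairwise testing by
  default; with many groups the family-wise error grows, and the
  Bonferroni flag is a blunt remedy.
- The classifier cannot distinguish a within-biotype mutation at a
  diagnostic site from another species; both route to `other_species`.
- The packaged marker offsets are synthetic stand-ins; results on real
  amplicons depend entirely on a user-supplied marker definition.
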