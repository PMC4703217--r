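# aphidbiotype

Life-table demography and mitochondrial SNP biotyping of the
cotton-melon aphid (*Aphis gossypii*).

Host-specialized biotypes of *A. gossypii* — a cotton race and a
cucumber race — look identical but differ sharply in whether they can
survive and reproduce after transfer to the other host. This package
implements the two analyses such studies rest on, for entomologists and
pest-management researchers:

1. **Host-transfer demography.** Daily cohort records (number alive,
   nymphs produced) are converted into the classical life-table
   schedule, where for age *x* in days, *l<sub>x</sub>* is the
   proportion of the founding cohort alive and *m<sub>x</sub>* the mean
   offspring per surviving female per day (all individuals are
   parthenogenetic females). The three demographic parameters follow:

   - net reproductive rate  R₀ = Σ l<sub>x</sub> m<sub>x</sub>
   - mean generation time  T = Σ x l<sub>x</sub> m<sub>x</sub> / Σ l<sub>x</sub> m<sub>x</sub>
   - intrinsic rate of increase  r<sub>m</sub> = ln R₀ / T

   Parameters are computed per replicate and summarized as mean ± SD
   per treatment; treatments are compared with Mann–Whitney U and
   Kruskal–Wallis tests, `*`/`**` significance marks, and compact
   letter displays. A cohort that never reproduces has R₀ = 0 and
   undefined T and r<sub>m</sub> (reported as a dash and excluded from
   those means), and r<sub>m</sub> is negative whenever R₀ < 1 — the
   signature of a collapsing transfer treatment.

2. **Molecular biotype diagnosis.** A cytb–16S mitochondrial fragment,
   anchored by the CytbF/16SR primer pair, carries five diagnostic
   single-nucleotide sites: T,A,A,T,T in the cotton biotype and
   C,G,G,C,C in the cucumber biotype. The classifier locates the
   forward primer on either strand (tolerating a configurable number of
   mismatches), reads the five sites, and calls each sequence `cotton`,
   `cucumber`, `other_species` (no primer site, or an off-pattern
   genotype), or `ambiguous` (an IUPAC ambiguity code at a diagnostic
   site). Calls are aggregated into proportion tables by collection
   time, host plant, and morph — the layout of a field survey.

A synthetic-data module simulates both kinds of input with known ground
truth (Bernoulli daily survival, Poisson fecundity; primer-flanked
amplicons with configurable background noise), so the entire pipeline
is testable without field collections.

## Worked example

Simulate 20 replicate cohorts of 10 nymphs under the default schedule
(5 pre-reproductive days at daily survival 0.98, then 10 reproductive
days at survival 0.97 and 4 offspring/survivor/day) and summarize:

```r
library(aphidbiotype)

cfg     <- cohort_sim_config(seed = 42)
cohorts <- simulate_cohorts(cfg, treatment = "natal host")
replicate_parameters(cohorts, pooled = TRUE)
#> <treatment_summary> natal host (n = 20 replicates, 0 without reproduction)
#>   R0 = 29.5 ± 3.7
#>   T  = 10.2 ± 0.2 d
#>   rm = 0.33 ± 0.01 /d
#>   pooled: R0 = 29.6, T = 10.2, rm = 0.33

analytic_truth(cfg)        # closed-form expectation of the same schedule
#>      R0     T    rm
#> 1  30.7  10.2 0.334
```

The simulated mean R₀ of 29.5 ± 3.7 recovers the analytic expectation
30.7 (well within one between-replicate SD), and r<sub>m</sub> ≈ 0.33/d
is the growth rate of a thriving aphid colony: about a 39% increase per
day. Classification works the same way end to end:

```r
marker <- default_marker()
sim    <- simulate_marker_sequences(
  sequence_sim_config(n_cotton = 12, n_cucumber = 6, n_other = 2, seed = 88),
  marker
)
calls  <- classify_batch(sim$sequences, marker)
all(calls$call == sim$truth$true_class)
#> [1] TRUE
```

`run_demography()` and `run_biotyping()` wire these stages into
file-to-file pipelines, and `inst/cli/aphidbiotype.R` exposes them as
shell subcommands (`lifetable`, `compare`, `biotype`, `survey`,
`simulate-cohorts`, `simulate-seqs`). A demo cohort CSV, a marker
config, and two synthetic reference fragments ship under
`inst/extdata/`.

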