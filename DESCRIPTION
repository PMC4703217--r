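Package: aphidbiotype
Title: Life-Table Demography and Mitochondrial SNP Biotyping of
    Cotton-Melon Aphids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for host-transfer demographic analysis of the
    cotton-melon aphid (Aphis gossypii) and for molecular biotype
    diagnosis from a cytb-16S mitochondrial marker fragment. Converts
    daily cohort records into age-specific survival (lx) and fecundity
    (mx) schedules and computes the net reproductive rate R0 = sum(lx mx),
    mean generation time T, and the intrinsic rate of increase
    rm = ln(R0)/T per replicate and per treatment; compares treatments
    with Mann-Whitney U and Kruskal-Wallis tests, star marks, and compact
    letter displays. Classifies marker fragments into cotton biotype,
    cucumber biotype, or other aphid species from five diagnostic
    nucleotide sites anchored by the amplification primers, and
    aggregates calls into host-by-season proportion tables. A synthetic
    data module simulates cohorts (Bernoulli survival, Poisson fecundity)
    and marker amplicon sets with known ground truth so the whole
    pipeline is testable without field collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
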