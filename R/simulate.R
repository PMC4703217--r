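#' Configuration for cohort simulation
#'
#' Describes a host-transfer treatment as a day-by-day stochastic
#' schedule: each individual alive at the previous check survives day x
#' with probability `survival_probs[x]` (independent Bernoulli), and
#' each survivor produces a Poisson number of offspring with mean
#' `fecundity_means[x]`. The defaults emulate an aphid cohort on its
#' natal host: 10 first-stadium nymphs, a 5-day pre-reproductive period
#' at daily survival 0.98, then 10 reproductive days at survival 0.97
#' producing on average 4 nymphs per survivor per day, for 20
#' replicates. The analytic expectation of this schedule is R0 = 30.7
#' with T about 10.3 days — the scale observed for cotton-biotype
#' aphids on cotton.
#'
#' @param survival_probs Per-day survival probabilities in `[0, 1]`.
#' @param fecundity_means Per-day expected offspring per survivor
#'   (>= 0); same length as `survival_probs`.
#' @param n_individuals Nymphs founding each cohort (protocol: 8-10).
#' @param n_replicates Number of cohorts (protocol: 10-30).
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(survival_probs = c(rep(0.98, 5), rep(0.97, 10)),
                              fecundity_means = c(rep(0, 5), rep(4, 10)),
                              n_individuals = 10,
                              n_replicates = 20,
                              seed = 1L) {
  if (length(survival_probs) != length(fecundity_means)) {
    abort("`survival_probs` and `fecundity_means` must have equal length.")
  }
  if (any(survival_probs < 0 | survival_probs > 1)) {
    abort("Survival probabilities must lie in [0, 1].")
  }
  if (any(fecundity_means < 0)) abort("Fecundity means must be >= 0.")
  if (n_individuals < 1 || n_replicates < 1) {
    abort("`n_individuals` and `n_replicates` must be positive.")
  }
  structure(
    list(
      survival_probs = survival_probs,
      fecundity_means = fecundity_means,
      n_individuals = as.integer(n_individuals),
      n_replicates = as.integer(n_replicates),
      seed = as.integer(seed)
    ),
    class = "cohort_sim_config"
  )
}

#' Simulate daily cohort records
#'
#' Draws `n_replicates` cohorts under a [cohort_sim_config()]. Each
#' individual's survival is an independent Bernoulli chain over the
#' day-specific probabilities; offspring counts are Poisson per survivor.
#' Every simulated cohort satisfies the cohort invariants (days 1..k,
#' non-increasing `n_alive`, zero offspring after extinction), and the
#' same seed reproduces the same cohorts exactly.
#'
#' @param config A [cohort_sim_config()].
#' @param treatment Optional treatment label attached to each cohort.
#' @return A list of [cohort()] objects.
#' @export
simulate_cohorts <- function(config, treatment = NA_character_) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  k <- length(config$survival_probs)
  lapply(seq_len(config$n_replicates), function(rep) {
    alive <- config$n_individuals
    n_alive <- integer(k)
    n_off <- integer(k)
    for (x in seq_len(k)) {
      alive <- rbinom(1, alive, config$survival_probs[x])
      n_alive[x] <- alive
      n_off[x] <- if (alive > 0 && config$fecundity_means[x] > 0) {
        rpois(1, alive * config$fecundity_means[x])
      } else {
        0L
      }
    }
    cohort(
      replicate_id = sprintf("sim%03d", rep),
      initial_n = config$n_individuals,
      day = seq_len(k),
      n_alive = n_alive,
      n_offspring = n_off,
      treatment = treatment
    )
  })
}

#' Analytic expectations for a simulated treatment
#'
#' The closed-form life-table parameters implied by a
#' [cohort_sim_config()]: the expected schedule has
#' `l_x = prod(p_1..p_x)` and `m_x = f_x`, so
#' `E[R0] = sum_x prod(p_i, i <= x) * f_x`, with T and rm derived from
#' that schedule by the usual formulas. Per-replicate R0 computed from
#' simulated cohorts is unbiased for this value, which makes the pair a
#' parameter-recovery oracle. All-zero fecundity (or immediate
#' extinction) gives R0 = 0 with undefined T and rm.
#'
#' @param config A [cohort_sim_config()].
#' @return A one-row tibble: `R0`, `T`, `rm`.
#' @export
analytic_truth <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  l_x <- cumprod(config$survival_probs)
  w <- l_x * config$fecundity_means
  r0 <- sum(w)
  if (r0 <= 0) {
    return(tibble::tibble(R0 = 0, T = NA_real_, rm = NA_real_))
  }
  tt <- sum(seq_along(w) * w) / r0
  tibble::tibble(R0 = r0, T = tt, rm = log(r0) / tt)
}

#' Configuration for marker-amplicon simulation
#'
#' Describes a synthetic field collection for the biotype classifier:
#' `n_cotton` and `n_cucumber` amplifiable fragments carrying the
#' respective diagnostic patterns, and `n_other` sequences from other
#' aphid species whose primer-binding region has diverged (so the assay
#' does not amplify them). `background_noise` is the per-site
#' substitution probability applied outside primer regions and
#' diagnostic sites, emulating neutral variation along the fragment.
#'
#' @param n_cotton,n_cucumber,n_other Record counts (>= 0).
#' @param background_noise Substitution probability in `[0, 1)`,
#'   default 0.
#' @param fragment_length Total record length in bases including both
#'   primer regions (default 200).
#' @param seed Integer RNG seed.
#' @return A list of class `sequence_sim_config`.
#' @export
sequence_sim_config <- function(n_cotton = 20, n_cucumber = 10, n_other = 5,
                                background_noise = 0,
                                fragment_length = 200,
                                seed = 1L) {
  if (any(c(n_cotton, n_cucumber, n_other) < 0)) {
    abort("Record counts must be >= 0.")
  }
  if (background_noise < 0 || background_noise >= 1) {
    abort("`background_noise` must lie in [0, 1).")
  }
  structure(
    list(
      n_cotton = as.integer(n_cotton),
      n_cucumber = as.integer(n_cucumber),
      n_other = as.integer(n_other),
      background_noise = background_noise,
      fragment_length = as.integer(fragment_length),
      seed = as.integer(seed)
    ),
    class = "sequence_sim_config"
  )
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1)
}

#' Simulate marker amplicons with known biotype truth
#'
#' Generates primer-flanked fragments: forward primer, then an anchored
#' region carrying the biotype's diagnostic pattern at the marker's
#' offsets, ending in the reverse complement of the reverse primer.
#' Background noise substitutes non-diagnostic, non-primer sites
#' independently. Other-species records are random sequences of the
#' same length with no primer site, so they fail amplification. Every
#' second record is emitted reverse-complemented, forcing the
#' classifier's strand handling to be exercised; the truth table
#' records each sequence's class and emitted orientation. The same seed
#' yields byte-identical output.
#'
#' @param config A [sequence_sim_config()].
#' @param marker A [marker_definition()]; `fragment_length` must exceed
#'   both primers plus the last diagnostic offset.
#' @return A list with `sequences` (a named `Biostrings::DNAStringSet`)
#'   and `truth` (tibble: `id`, `true_class`, `emitted_orientation`).
#' @export
simulate_marker_sequences <- function(config, marker = default_marker()) {
  stopifnot(inherits(config, "sequence_sim_config"))
  fwd <- marker$forward_primer
  rev_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(marker$reverse_primer))
  )
  core_len <- config$fragment_length - nchar(fwd) - nchar(rev_rc)
  if (core_len < max(marker$offsets)) {
    abort(sprintf(
      "fragment_length %d leaves %d anchored bases before the reverse primer; the last diagnostic site is at %d.",
      config$fragment_length, core_len, max(marker$offsets)
    ))
  }
  set.seed(config$seed)
  classes <- rep(c("cotton", "cucumber", "other_species"),
                 times = c(config$n_cotton, config$n_cucumber, config$n_other))
  pats <- list(
    cotton = strsplit(marker$cotton_pattern, "")[[1]],
    cucumber = strsplit(marker$cucumber_pattern, "")[[1]]
  )
  make_one <- function(cls) {
    if (cls == "other_species") {
      # divergent species: no primer site anywhere
      repeat {
        s <- random_bases(config$fragment_length)
        hit <- best_primer_hit(s, fwd, marker$max_primer_mismatches)
        rc <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(s))
        )
        hit_rc <- best_primer_hit(rc, fwd, marker$max_primer_mismatches)
        if (is.null(hit) && is.null(hit_rc)) {
          return(s)
        }
      }
    }
    core <- strsplit(random_bases(core_len), "")[[1]]
    if (config$background_noise > 0) {
      flip <- runif(core_len) < config$background_noise
      for (i in which(flip)) core[i] <- substitute_base(core[i])
    }
    core[marker$offsets] <- pats[[cls]]
    paste0(fwd, paste(core, collapse = ""), rev_rc)
  }
  seqs <- vapply(classes, make_one, character(1), USE.NAMES = FALSE)
  orientation <- rep(c("forward", "reverse_complement"),
                     length.out = length(seqs))
  flip <- orientation == "reverse_complement"
  if (any(flip)) {
    seqs[flip] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[flip]))
    )
  }
  ids <- sprintf("syn%04d", seq_along(seqs))
  dss <- Biostrings::DNAStringSet(setNames(seqs, ids))
  list(
    sequences = dss,
    truth = tibble::tibble(
      id = ids,
      true_class = classes,
      emitted_orientation = orientation
    )
  )
}

#' Write simulated amplicons to FASTA with a truth sidecar
#'
#' @param sim Output of [simulate_marker_sequences()].
#' @param fasta_path,truth_path Output paths (FASTA and CSV).
#' @return `fasta_path`, invisibly.
#' @export
write_simulated_sequences <- function(sim, fasta_path, truth_path = NULL) {
  Biostrings::writeXStringSet(sim$sequences, fasta_path, width = 70)
  if (!is.null(truth_path)) readr::write_csv(sim$truth, truth_path)
  invisible(fasta_path)
}
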