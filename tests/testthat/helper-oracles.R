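# Independent oracles and small fixture builders shared across tests.

# Exact two-sided Mann-Whitney p by full enumeration of rank splits.
# Valid for tie-free samples only; independent of stats::wilcox.test.
mw_enumeration_oracle <- function(a, b) {
  na <- length(a)
  n <- na + length(b)
  stopifnot(anyDuplicated(c(a, b)) == 0)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(na)]) - na * (na + 1) / 2
  splits <- utils::combn(n, na)
  us <- apply(splits, 2, function(ix) sum(ix) - na * (na + 1) / 2)
  p <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  list(U = u_obs, p = p)
}

# Brute-force life-table parameters by explicit looping over rows.
brute_force_params <- function(schedule) {
  r0 <- 0
  xw <- 0
  for (i in seq_len(nrow(schedule))) {
    w <- schedule$l_x[i] * schedule$m_x[i]
    r0 <- r0 + w
    xw <- xw + schedule$x[i] * w
  }
  if (r0 == 0) {
    return(list(R0 = 0, T = NA_real_, rm = NA_real_))
  }
  tt <- xw / r0
  list(R0 = r0, T = tt, rm = log(r0) / tt)
}

# A deterministic three-day cohort used across lifetable tests.
tiny_cohort <- function(id = "r1") {
  cohort(id, 2, day = 1:3, n_alive = c(2, 2, 0), n_offspring = c(0, 4, 0))
}

# Random valid schedule for property tests (may or may not reproduce).
random_schedule <- function(n_days = 8) {
  l <- cumprod(runif(n_days, 0.6, 1))
  m <- ifelse(runif(n_days) < 0.4, 0, runif(n_days, 0, 3))
  tibble::tibble(x = seq_len(n_days), l_x = l, m_x = m)
}

reverse_complement_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
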