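#' Build an age-specific survival and fecundity schedule
#'
#' Converts one cohort's daily records into the classical life-table
#' schedule: for each age x (days), l_x is the proportion of the original
#' cohort still alive and m_x the mean number of offspring per surviving
#' individual that day. Cotton-melon aphids reproduce by apomictic
#' parthenogenesis, so every individual is female and no sex-ratio
#' adjustment applies; m_x is simply offspring counted that day divided
#' by the number alive that day (0 once the cohort is extinct).
#'
#' Days skipped between two checks are filled in by carrying the last
#' `n_alive` forward with `m_x = 0`, so that schedules from occasionally
#' lapsed daily checks still have one row per day.
#'
#' @param cohort A [cohort()] object.
#' @return A tibble of class `life_table` with columns `x` (age, days),
#'   `l_x` (proportion surviving, in 0..1, non-increasing) and `m_x`
#'   (offspring per survivor per day).
#' @examples
#' ch <- cohort("r1", 2, day = 1:3, n_alive = c(2, 2, 0),
#'              n_offspring = c(0, 4, 0))
#' build_life_table(ch)
#' @export
build_life_table <- function(cohort) {
  validate_cohort(cohort)
  obs <- cohort$observations
  days <- seq(min(obs$day), max(obs$day))
  idx <- match(days, obs$day)
  # carry n_alive forward over skipped days; no offspring on those days
  n_alive <- obs$n_alive[idx]
  filled <- cumsum(!is.na(n_alive))
  n_alive <- obs$n_alive[filled]
  n_off <- ifelse(is.na(idx), 0L, obs$n_offspring[idx])

  schedule <- tibble::tibble(
    x = days,
    l_x = n_alive / cohort$initial_n,
    m_x = ifelse(n_alive > 0, n_off / n_alive, 0)
  )
  class(schedule) <- c("life_table", class(schedule))
  schedule
}

validate_schedule <- function(schedule) {
  needed <- c("x", "l_x", "m_x")
  if (!all(needed %in% names(schedule))) {
    abort("A life-table schedule needs columns x, l_x, m_x.")
  }
  if (nrow(schedule) == 0) abort("Empty life-table schedule.")
  if (any(diff(schedule$x) <= 0)) abort("Schedule ages must be increasing.")
  if (any(schedule$l_x < 0 | schedule$l_x > 1)) {
    abort("l_x must lie in [0, 1].")
  }
  if (any(diff(schedule$l_x) > 1e-12)) abort("l_x must be non-increasing.")
  if (any(!is.finite(schedule$m_x)) || any(schedule$m_x < 0)) {
    abort("m_x must be finite and non-negative.")
  }
  invisible(schedule)
}

#' Net reproductive rate R0
#'
#' R0 = sum over ages of l_x * m_x: the expected lifetime number of
#' offspring per newborn individual. R0 is 0 for a cohort that never
#' reproduced.
#'
#' @param schedule A life-table schedule from [build_life_table()] (or
#'   any data frame with columns `x`, `l_x`, `m_x`).
#' @return A single non-negative number.
#' @export
net_reproductive_rate <- function(schedule) {
  validate_schedule(schedule)
  sum(schedule$l_x * schedule$m_x)
}

#' Mean generation time T
#'
#' T = sum(x l_x m_x) / sum(l_x m_x): the fecundity-weighted mean age of
#' reproduction, in days. Undefined (NA) when the cohort never
#' reproduced (R0 = 0).
#'
#' @inheritParams net_reproductive_rate
#' @return Generation time in days, or `NA_real_` when R0 = 0.
#' @export
generation_time <- function(schedule) {
  validate_schedule(schedule)
  r0 <- sum(schedule$l_x * schedule$m_x)
  if (r0 <= 0) {
    return(NA_real_)
  }
  sum(schedule$x * schedule$l_x * schedule$m_x) / r0
}

#' Intrinsic rate of increase rm
#'
#' The per-day exponential growth rate, approximated as
#' `rm = ln(R0) / T`. Positive when R0 > 1, zero at R0 = 1, and negative
#' when R0 < 1 (a declining population, as seen when aphids are
#' transferred to a non-host). Undefined (NA) when R0 = 0, since ln 0
#' diverges; such treatments are reported with a dash.
#'
#' @param R0 Net reproductive rate(s), >= 0.
#' @param T Mean generation time(s) in days, > 0.
#' @return rm in units of per day; `NA_real_` where `R0` is 0 or `T`
#'   undefined.
#' @examples
#' intrinsic_rate_of_increase(30.7, 9.9) # about 0.35 / day
#' @export
intrinsic_rate_of_increase <- function(R0, T) {
  if (any(R0 < 0, na.rm = TRUE)) abort("R0 must be non-negative.")
  if (any(T <= 0, na.rm = TRUE)) abort("T must be positive.")
  ifelse(is.na(R0) | is.na(T) | R0 == 0, NA_real_, log(R0) / T)
}

#' Demographic parameters for one cohort
#'
#' Computes R0, T and rm from a cohort's life-table schedule. Replicates
#' in which no individual reproduced have R0 = 0 and undefined T and rm
#' (`defined = FALSE`).
#'
#' @param cohort A [cohort()] object, or a prebuilt life-table schedule.
#' @return A one-row tibble: `replicate_id`, `R0`, `T`, `rm`, `defined`.
#' @export
demographic_params <- function(cohort) {
  if (inherits(cohort, "cohort")) {
    id <- cohort$replicate_id
    schedule <- build_life_table(cohort)
  } else {
    id <- NA_character_
    schedule <- cohort
  }
  r0 <- net_reproductive_rate(schedule)
  tt <- generation_time(schedule)
  tibble::tibble(
    replicate_id = id,
    R0 = r0,
    T = tt,
    rm = if (r0 > 0) intrinsic_rate_of_increase(r0, tt) else NA_real_,
    defined = r0 > 0
  )
}

#' Treatment summary of life-table parameters
#'
#' Computes per-replicate demographic parameters, then their mean and
#' sample SD across replicates — the "mean ± SD" a host-transfer table
#' prints. Replicates with R0 = 0 contribute 0 to the R0 mean but are
#' excluded from the T and rm means (their count is reported as
#' `n_undefined`), because T and rm do not exist for a cohort that never
#' reproduced.
#'
#' A pooled mode is also provided: parameters computed once from the
#' treatment-mean schedule (per-day mean l_x and mean m_x across
#' replicates, shorter replicates carried forward at l_x of extinction).
#' Published rm values are sometimes consistent with one mode and
#' sometimes the other; per-replicate is the default because printed SDs
#' require replicate-level values.
#'
#' @param cohorts A list of [cohort()] objects (>= 1).
#' @param label Treatment label; defaults to the cohorts' common
#'   `treatment` field when present.
#' @param pooled If `TRUE`, additionally compute pooled parameters from
#'   the mean schedule.
#' @return An object of class `treatment_summary`: a list with `label`,
#'   `n_replicates`, `n_undefined`, `params` (per-replicate tibble),
#'   `summary` (one-row tibble of means and SDs) and, when requested,
#'   `pooled` (one-row tibble).
#' @export
replicate_parameters <- function(cohorts, label = NULL, pooled = FALSE) {
  if (length(cohorts) < 1) abort("Need at least one cohort.")
  params <- dplyr::bind_rows(lapply(cohorts, demographic_params))
  if (is.null(label)) {
    trts <- unique(vapply(cohorts, `[[`, character(1), "treatment"))
    label <- if (length(trts) == 1 && !is.na(trts)) trts else "treatment"
  }
  defined <- params[params$defined, ]
  smry <- tibble::tibble(
    treatment = label,
    n_reps = nrow(params),
    R0_mean = mean(params$R0),
    R0_sd = if (nrow(params) > 1) sd(params$R0) else 0,
    T_mean = if (nrow(defined) > 0) mean(defined$T) else NA_real_,
    T_sd = if (nrow(defined) > 1) sd(defined$T) else
      ifelse(nrow(defined) == 1, 0, NA_real_),
    rm_mean = if (nrow(defined) > 0) mean(defined$rm) else NA_real_,
    rm_sd = if (nrow(defined) > 1) sd(defined$rm) else
      ifelse(nrow(defined) == 1, 0, NA_real_),
    n_undefined = sum(!params$defined)
  )
  out <- list(
    label = label,
    n_replicates = nrow(params),
    n_undefined = sum(!params$defined),
    params = params,
    summary = smry
  )
  if (pooled) {
    out$pooled <- pooled_parameters(cohorts, label)
  }
  structure(out, class = "treatment_summary")
}

# parameters from the treatment-mean schedule
pooled_parameters <- function(cohorts, label) {
  schedules <- lapply(cohorts, build_life_table)
  max_day <- max(vapply(schedules, function(s) max(s$x), numeric(1)))
  grid <- lapply(schedules, function(s) {
    idx <- pmin(pmax(findInterval(seq_len(max_day), s$x), 1L), nrow(s))
    tibble::tibble(
      x = seq_len(max_day),
      l_x = s$l_x[idx],
      # m_x applies only on observed days; carried-forward tail adds 0
      m_x = ifelse(seq_len(max_day) %in% s$x, s$m_x[idx], 0)
    )
  })
  mean_sched <- tibble::tibble(
    x = seq_len(max_day),
    l_x = rowMeans(vapply(grid, `[[`, numeric(max_day), "l_x")),
    m_x = rowMeans(vapply(grid, `[[`, numeric(max_day), "m_x"))
  )
  p <- demographic_params(mean_sched)
  tibble::tibble(treatment = label, R0 = p$R0, T = p$T, rm = p$rm)
}

#' @export
print.treatment_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<treatment_summary> %s (n = %d replicates, %d without reproduction)\n",
    x$label, x$n_replicates, x$n_undefined
  ))
  cat(sprintf("  R0 = %s\n", fmt_mean_sd(s$R0_mean, s$R0_sd, 1)))
  cat(sprintf("  T  = %s d\n", fmt_mean_sd(s$T_mean, s$T_sd, 1)))
  cat(sprintf("  rm = %s /d\n", fmt_mean_sd(s$rm_mean, s$rm_sd, 2)))
  if (!is.null(x$pooled)) {
    cat(sprintf(
      "  pooled: R0 = %.1f, T = %.1f, rm = %.2f\n",
      x$pooled$R0, x$pooled$T, x$pooled$rm
    ))
  }
  invisible(x)
}

#' Mean survival percentage at given days
#'
#' For each requested day, computes the per-replicate survival percentage
#' `100 * n_alive(day) / initial_n` and summarizes it as mean ± sample SD
#' across replicates — the layout of a "survival after transfer" table.
#' Days after a replicate's last check carry the final `n_alive` forward;
#' a day before a replicate's first check is an error.
#'
#' @param cohorts A list of [cohort()] objects.
#' @param day Integer vector of days to evaluate.
#' @return A tibble with columns `day`, `mean`, `sd`, `n` and a
#'   list-column `percent` of the per-replicate percentages.
#' @export
survival_percent <- function(cohorts, day) {
  day <- as.integer(day)
  per_rep <- lapply(cohorts, function(ch) {
    validate_cohort(ch)
    obs <- ch$observations
    if (any(day < min(obs$day))) {
      abort(sprintf(
        "Cohort '%s': day %d precedes the first observation (day %d).",
        ch$replicate_id, min(day), min(obs$day)
      ))
    }
    idx <- pmin(findInterval(day, obs$day), nrow(obs))
    100 * obs$n_alive[idx] / ch$initial_n
  })
  mat <- do.call(rbind, per_rep) # replicates x days
  tibble::tibble(
    day = day,
    mean = colMeans(mat),
    sd = if (nrow(mat) > 1) apply(mat, 2, sd) else rep(0, length(day)),
    n = nrow(mat),
    percent = lapply(seq_along(day), function(j) mat[, j])
  )
}
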