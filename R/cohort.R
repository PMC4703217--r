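#' Construct a daily cohort record
#'
#' A cohort is one replicate of a host-transfer treatment: 8-10
#' first-stadium nymphs placed on an excised leaf, checked daily, newborn
#' nymphs counted and removed, until all individuals have died. Age `day`
#' is 1 at the first daily check after cohort initiation (the founding
#' adults are removed after 24 h).
#'
#' @param replicate_id Identifier for the replicate.
#' @param initial_n Number of first-stadium nymphs that started the cohort
#'   (positive integer).
#' @param day Integer vector of ages in days (>= 1), strictly increasing.
#' @param n_alive Number of cohort members alive at each daily check;
#'   non-increasing, never above `initial_n`.
#' @param n_offspring Newborn nymphs counted (and removed) at each check;
#'   must be 0 on days when `n_alive` is 0.
#' @param treatment Optional treatment label (e.g. "Cotton-cucumber").
#' @return An object of class `cohort`: a list with `replicate_id`,
#'   `initial_n`, `treatment`, and an `observations` tibble with columns
#'   `day`, `n_alive`, `n_offspring`.
#' @examples
#' cohort("r1", 10, day = 1:3, n_alive = c(10, 8, 0),
#'        n_offspring = c(0, 4, 0))
#' @export
cohort <- function(replicate_id, initial_n, day, n_alive, n_offspring,
                   treatment = NA_character_) {
  obs <- tibble::tibble(
    day = as.integer(day),
    n_alive = as.integer(n_alive),
    n_offspring = as.integer(n_offspring)
  )
  out <- structure(
    list(
      replicate_id = as.character(replicate_id),
      initial_n = as.integer(initial_n),
      treatment = as.character(treatment),
      observations = obs
    ),
    class = "cohort"
  )
  validate_cohort(out)
}

#' Validate a cohort's internal consistency
#'
#' Checks the invariants of daily cohort records: strictly increasing
#' observation days starting at age >= 1, `n_alive` bounded by `initial_n`
#' and non-increasing over time, non-negative offspring counts, and no
#' offspring recorded after the cohort is extinct.
#'
#' @param x A [cohort()] object.
#' @return `x`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending day.
#' @export
validate_cohort <- function(x) {
  if (!inherits(x, "cohort")) {
    abort("`x` must be a cohort object.")
  }
  obs <- x$observations
  id <- x$replicate_id
  if (nrow(obs) == 0) {
    abort(sprintf("Cohort '%s': empty observation list.", id))
  }
  if (is.na(x$initial_n) || x$initial_n < 1) {
    abort(sprintf("Cohort '%s': initial_n must be a positive integer.", id))
  }
  if (anyNA(obs)) {
    abort(sprintf("Cohort '%s': missing values in observations.", id))
  }
  if (any(obs$day < 1)) {
    abort(sprintf("Cohort '%s': days must be >= 1.", id))
  }
  if (any(diff(obs$day) <= 0)) {
    bad <- obs$day[which(diff(obs$day) <= 0)[1] + 1]
    abort(sprintf(
      "Cohort '%s': days must be strictly increasing (day %d).", id, bad
    ))
  }
  if (any(obs$n_alive < 0) || any(obs$n_offspring < 0)) {
    abort(sprintf("Cohort '%s': negative counts.", id))
  }
  if (any(obs$n_alive > x$initial_n)) {
    bad <- obs$day[which(obs$n_alive > x$initial_n)[1]]
    abort(sprintf(
      "Cohort '%s': n_alive exceeds initial_n on day %d.", id, bad
    ))
  }
  if (any(diff(obs$n_alive) > 0)) {
    bad <- obs$day[which(diff(obs$n_alive) > 0)[1] + 1]
    abort(sprintf(
      "Cohort '%s': n_alive increases on day %d; survivors cannot reappear.",
      id, bad
    ))
  }
  if (any(obs$n_offspring > 0 & obs$n_alive == 0)) {
    bad <- obs$day[which(obs$n_offspring > 0 & obs$n_alive == 0)[1]]
    abort(sprintf(
      "Cohort '%s': offspring recorded with no survivors on day %d.", id, bad
    ))
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %s%s: %d nymphs, days %d-%d, %d offspring total\n",
    x$replicate_id,
    if (is.na(x$treatment)) "" else paste0(" [", x$treatment, "]"),
    x$initial_n,
    min(x$observations$day), max(x$observations$day),
    sum(x$observations$n_offspring)
  ))
  invisible(x)
}

#' Read daily cohort records from CSV
#'
#' Expects one row per replicate-day with columns
#' `replicate_id,day,n_alive,n_offspring` (header required) and an
#' optional treatment column. The initial cohort size is not stored in
#' the file; it is taken as `n_alive` at the first observed day of each
#' replicate unless `initial_n` is given.
#'
#' @param path Path to the CSV file.
#' @param treatment_col Optional name of a column holding the treatment
#'   label for each row (constant within a replicate).
#' @param initial_n Optional single value or named vector (by
#'   replicate id) overriding the inferred initial cohort size.
#' @return A list of [cohort()] objects, one per replicate, in first
#'   order of appearance.
#' @export
read_cohorts <- function(path, treatment_col = NULL, initial_n = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("replicate_id", "day", "n_alive", "n_offspring")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "Cohort CSV %s is missing column(s): %s.",
      path, paste(missing, collapse = ", ")
    ))
  }
  if (nrow(df) == 0) {
    abort(sprintf("Cohort CSV %s contains no data rows.", path))
  }
  if (!is.null(treatment_col) && !treatment_col %in% names(df)) {
    abort(sprintf("Treatment column '%s' not found in %s.", treatment_col, path))
  }
  ids <- unique(df$replicate_id)
  lapply(ids, function(id) {
    rows <- df[df$replicate_id == id, ]
    rows <- rows[order(rows$day), ]
    n0 <- if (is.null(initial_n)) {
      rows$n_alive[1]
    } else if (!is.null(names(initial_n))) {
      unname(initial_n[[as.character(id)]])
    } else {
      initial_n
    }
    trt <- if (is.null(treatment_col)) NA_character_ else
      as.character(rows[[treatment_col]][1])
    cohort(id, n0, rows$day, rows$n_alive, rows$n_offspring, treatment = trt)
  })
}

#' Write cohorts to a CSV of daily records
#'
#' Inverse of [read_cohorts()]: one row per replicate-day, columns
#' `replicate_id,day,n_alive,n_offspring` plus `treatment` when any
#' cohort carries a label.
#'
#' @param cohorts A list of [cohort()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohorts <- function(cohorts, path) {
  rows <- lapply(cohorts, function(ch) {
    tibble::tibble(
      replicate_id = ch$replicate_id,
      ch$observations,
      treatment = ch$treatment
    )
  })
  df <- dplyr::bind_rows(rows)
  if (all(is.na(df$treatment))) df$treatment <- NULL
  readr::write_csv(df, path)
  invisible(path)
}
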