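#' Aggregate biotype calls into a proportion table
#'
#' Builds the survey layout of a field biotyping campaign: one row per
#' grouping-key combination (typically collection time, host plant,
#' morph) with the total number of individuals and the percentage
#' called cotton biotype, cucumber biotype, and other aphid species.
#' Ambiguous calls cannot be attributed to any class, so they are
#' excluded from the percentage denominator and reported in their own
#' `n_ambiguous` column; the three raw fractions of each row then sum to
#' 1 exactly. Rounded display percentages (integer, half-up) are carried
#' alongside the raw fractions.
#'
#' @param calls A tibble from [classify_batch()]; must carry the
#'   grouping columns (join metadata first or pass it to
#'   `classify_batch()`).
#' @param group_by Character vector of grouping column names, e.g.
#'   `c("collection_time", "host", "morph")`.
#' @return A tibble of class `survey_table` with the grouping columns,
#'   `total`, `n_ambiguous`, raw fractions `frac_cotton`,
#'   `frac_cucumber`, `frac_other` and integer display percentages
#'   `pct_cotton`, `pct_cucumber`, `pct_other`.
#' @export
summarize_survey <- function(calls, group_by) {
  calls <- tibble::as_tibble(calls)
  missing <- setdiff(group_by, names(calls))
  if (length(missing) > 0) {
    abort(sprintf(
      "Grouping column(s) not present in calls: %s.",
      paste(missing, collapse = ", ")
    ))
  }
  if (nrow(calls) == 0) {
    out <- tibble::tibble(
      total = integer(), n_ambiguous = integer(),
      frac_cotton = numeric(), frac_cucumber = numeric(),
      frac_other = numeric(), pct_cotton = numeric(),
      pct_cucumber = numeric(), pct_other = numeric()
    )
    class(out) <- c("survey_table", class(out))
    return(out)
  }
  for (key in group_by) {
    bad <- is.na(calls[[key]])
    if (any(bad)) {
      abort(sprintf(
        "Record '%s' is missing grouping key '%s'.",
        calls$id[which(bad)[1]], key
      ))
    }
  }
  out <- calls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      total = sum(.data$call != "ambiguous"),
      n_ambiguous = sum(.data$call == "ambiguous"),
      frac_cotton = sum(.data$call == "cotton") / .data$total,
      frac_cucumber = sum(.data$call == "cucumber") / .data$total,
      frac_other = sum(.data$call == "other_species") / .data$total,
      .groups = "drop"
    )
  empty <- out$total == 0
  if (any(empty)) {
    warn(sprintf(
      "%d group(s) contained only ambiguous calls and were dropped.",
      sum(empty)
    ))
    out <- out[!empty, ]
  }
  out$pct_cotton <- round_half_up(100 * out$frac_cotton)
  out$pct_cucumber <- round_half_up(100 * out$frac_cucumber)
  out$pct_other <- round_half_up(100 * out$frac_other)
  class(out) <- c("survey_table", class(out))
  out
}

#' Render a survey table as TSV text
#'
#' Deterministic, idempotent serialization: grouping columns first, then
#' `total`, the three integer percentages, `n_ambiguous`, and the raw
#' fractions as auxiliary columns. Re-rendering the same table is
#' byte-identical.
#'
#' @param table A `survey_table` from [summarize_survey()].
#' @return A single TSV string (header + one line per row, trailing
#'   newline).
#' @export
render_table <- function(table) {
  keys <- setdiff(
    names(table),
    c("total", "n_ambiguous", "frac_cotton", "frac_cucumber", "frac_other",
      "pct_cotton", "pct_cucumber", "pct_other")
  )
  cols <- c(keys, "total", "pct_cotton", "pct_cucumber", "pct_other",
            "n_ambiguous", "frac_cotton", "frac_cucumber", "frac_other")
  df <- as.data.frame(table)[, cols, drop = FALSE]
  for (p in c("pct_cotton", "pct_cucumber", "pct_other")) {
    df[[p]] <- sprintf("%d", as.integer(df[[p]]))
  }
  for (f in c("frac_cotton", "frac_cucumber", "frac_other")) {
    df[[f]] <- sprintf("%.6f", df[[f]])
  }
  lines <- c(
    paste(cols, collapse = "\t"),
    vapply(seq_len(nrow(df)), function(i) {
      paste(vapply(df[i, , drop = FALSE], as.character, character(1)),
            collapse = "\t")
    }, character(1))
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}
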