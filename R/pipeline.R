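#' Write treatment parameter summaries as TSV
#'
#' Fixed column order
#' `treatment,n_reps,R0_mean,R0_sd,T_mean,T_sd,rm_mean,rm_sd,n_undefined`
#' so outputs diff cleanly across runs. Undefined means (treatments
#' where no replicate reproduced) are written as `NA`.
#'
#' @param summaries A list of `treatment_summary` objects from
#'   [replicate_parameters()].
#' @param path Output TSV path.
#' @return The combined summary tibble, invisibly.
#' @export
write_params_tsv <- function(summaries, path) {
  df <- dplyr::bind_rows(lapply(summaries, `[[`, "summary"))
  readr::write_tsv(df, path)
  invisible(df)
}

#' Run the demographic half of the pipeline
#'
#' Reads a daily cohort CSV, groups replicates by treatment, computes
#' per-treatment life-table parameter summaries, and (when more than one
#' treatment is present) compares each metric across treatments with a
#' Kruskal-Wallis test plus pairwise Mann-Whitney letters. Replicate
#' counts and undefined-parameter exclusions are logged to stderr;
#' results go only to the returned tibbles / output files.
#'
#' @param cohorts_csv Path to the cohort CSV
#'   (`replicate_id,day,n_alive,n_offspring` + treatment column).
#' @param treatment_col Name of the treatment column (default
#'   `"treatment"`); when absent, all replicates form one treatment.
#' @param out_params,out_comparisons Optional output TSV paths.
#' @param alpha Significance level for the letter display.
#' @param pooled Also compute pooled (treatment-mean schedule)
#'   parameters.
#' @return A list: `summaries` (list of `treatment_summary`), `params`
#'   (combined tibble), `comparisons` (tibble or `NULL`).
#' @export
run_demography <- function(cohorts_csv, treatment_col = "treatment",
                           out_params = NULL, out_comparisons = NULL,
                           alpha = 0.05, pooled = FALSE) {
  has_trt <- treatment_col %in% names(
    readr::read_csv(cohorts_csv, n_max = 0, show_col_types = FALSE)
  )
  cohorts <- read_cohorts(
    cohorts_csv,
    treatment_col = if (has_trt) treatment_col else NULL
  )
  trts <- vapply(cohorts, `[[`, character(1), "treatment")
  trts[is.na(trts)] <- "all"
  by_trt <- split(cohorts, factor(trts, levels = unique(trts)))
  summaries <- lapply(names(by_trt), function(lab) {
    s <- replicate_parameters(by_trt[[lab]], label = lab, pooled = pooled)
    message(sprintf(
      "treatment '%s': %d replicates, %d without reproduction",
      lab, s$n_replicates, s$n_undefined
    ))
    s
  })
  params <- dplyr::bind_rows(lapply(summaries, `[[`, "summary"))
  comparisons <- NULL
  if (length(summaries) > 1) {
    comparisons <- dplyr::bind_rows(lapply(c("R0", "T", "rm"), function(metric) {
      vals <- lapply(summaries, function(s) {
        v <- s$params[[metric]]
        v[s$params$defined | metric == "R0"]
      })
      names(vals) <- vapply(summaries, `[[`, character(1), "label")
      vals <- vals[lengths(vals) > 0]
      if (length(vals) < 2) {
        return(NULL)
      }
      kw <- kruskal_wallis(vals)
      cld <- pairwise_letters(vals, alpha = alpha)
      tibble::tibble(
        metric = metric,
        group = cld$group,
        mean = cld$mean,
        letters = cld$letters,
        kw_H = kw$statistic,
        kw_p = kw$p_value,
        kw_mark = significance_marks(kw$p_value)
      )
    }))
  }
  if (!is.null(out_params)) write_params_tsv(summaries, out_params)
  if (!is.null(out_comparisons) && !is.null(comparisons)) {
    readr::write_tsv(comparisons, out_comparisons)
  }
  list(summaries = summaries, params = params, comparisons = comparisons)
}

#' Run the biotyping half of the pipeline
#'
#' Classifies every sequence in a FASTA against a marker definition,
#' joins the collection metadata, and aggregates the calls into a
#' proportion table grouped by the requested keys. Per-class counts are
#' logged to stderr.
#'
#' @param fasta Path to the FASTA of marker amplicons (or a
#'   `DNAStringSet`).
#' @param marker A [marker_definition()] or path to a marker YAML
#'   config.
#' @param metadata A metadata tibble or path to the sidecar CSV
#'   (`id,host,collection_time,morph`).
#' @param group_by Grouping keys for the survey table.
#' @param out_calls,out_survey Optional output TSV paths.
#' @return A list: `calls` (per-sequence tibble), `survey`
#'   (`survey_table`, or `NULL` when the calls lack the grouping
#'   columns — e.g. no metadata was given).
#' @export
run_biotyping <- function(fasta, marker, metadata = NULL,
                          group_by = c("collection_time", "host", "morph"),
                          out_calls = NULL, out_survey = NULL) {
  if (is.character(marker)) marker <- read_marker(marker)
  if (is.character(metadata)) metadata <- read_sequence_metadata(metadata)
  calls <- classify_batch(fasta, marker, metadata = metadata)
  counts <- table(factor(
    calls$call,
    levels = c("cotton", "cucumber", "other_species", "ambiguous")
  ))
  message(paste(
    sprintf("%s: %d", names(counts), as.integer(counts)),
    collapse = ", "
  ))
  survey <- NULL
  if (all(group_by %in% names(calls))) {
    survey <- summarize_survey(calls, group_by = group_by)
  } else if (!is.null(out_survey)) {
    abort(sprintf(
      "Survey output needs metadata with grouping column(s): %s.",
      paste(setdiff(group_by, names(calls)), collapse = ", ")
    ))
  }
  if (!is.null(out_calls)) {
    readr::write_tsv(
      calls[, c("id", "call", "genotype", "orientation", "reason")],
      out_calls
    )
  }
  if (!is.null(out_survey) && !is.null(survey)) {
    writeLines(sub("\n$", "", render_table(survey)), out_survey)
  }
  list(calls = calls, survey = survey)
}
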