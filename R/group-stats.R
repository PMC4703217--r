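#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two treatments' life-table parameters or
#' survival percentages. The exact null distribution (full enumeration of
#' rank assignments) is used when the combined sample size is at most 10
#' and there are no ties; otherwise the normal approximation with tie
#' correction and continuity correction. Sample sizes in host-transfer
#' experiments (10-30 replicates) normally fall in the approximate
#' regime.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Combined sample size at or below which the exact
#'   distribution is used for tie-free data (default 10).
#' @return A list of class `comparison_result`: `statistic` (U for sample
#'   `a`), `p_value`, `method` ("exact" or "approximate"), `test`,
#'   `groups`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(a, b, exact_max = 10) {
  if (length(a) == 0 || length(b) == 0) {
    abort("Both samples must be non-empty.")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !ties && (length(a) + length(b)) <= exact_max
  res <- suppressWarnings(
    wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  structure(
    list(
      statistic = unname(res$statistic), # W equals U for sample a
      p_value = res$p.value,
      method = if (use_exact) "exact" else "approximate",
      test = "Mann-Whitney U",
      groups = c(deparse(substitute(a)), deparse(substitute(b)))
    ),
    class = "comparison_result"
  )
}

#' Kruskal-Wallis rank-sum test across treatments
#'
#' H statistic with tie correction and the chi-square approximation on
#' k - 1 degrees of freedom; used when more than two host-transfer
#' treatments are compared at once.
#'
#' @param groups A (preferably named) list of >= 2 non-empty numeric
#'   samples.
#' @return A `comparison_result` list: `statistic` (H), `p_value`,
#'   `method`, `test`, `groups`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("Need a list of at least two groups.")
  }
  if (any(lengths(groups) == 0)) abort("All groups must be non-empty.")
  res <- kruskal.test(groups)
  structure(
    list(
      statistic = unname(res$statistic),
      p_value = res$p.value,
      method = "approximate",
      test = "Kruskal-Wallis",
      groups = names(groups) %||% as.character(seq_along(groups)),
      df = unname(res$parameter)
    ),
    class = "comparison_result"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<%s> statistic = %.4g, p = %.4g (%s)%s\n",
    x$test, x$statistic, x$p_value, x$method, significance_marks(x$p_value)
  ))
  invisible(x)
}

#' Star marks for significance levels
#'
#' The table annotation convention: `**` for p < 0.01, `*` for
#' 0.01 <= p < 0.05, empty otherwise.
#'
#' @param p_value Numeric vector of p-values in 0..1.
#' @return Character vector of marks.
#' @examples
#' significance_marks(c(0.005, 0.03, 0.5)) # "**" "*" ""
#' @export
significance_marks <- function(p_value) {
  if (any(p_value < 0 | p_value > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  ifelse(p_value < 0.01, "**", ifelse(p_value < 0.05, "*", ""))
}

#' Compact letter display from pairwise Mann-Whitney tests
#'
#' Assigns letters to groups so that two groups share no letter if and
#' only if their two-sided pairwise Mann-Whitney comparison is
#' significant at `alpha` — the "values followed by different letters
#' differ significantly" notation. Letters are generated by the
#' insert-and-absorb method over groups sorted by descending mean, so
#' the highest-mean group always carries "a". Pairwise tests are
#' uncorrected for multiplicity by default (the convention the
#' annotation mirrors); set `correct = "bonferroni"` to adjust.
#'
#' @param groups Named list of >= 2 non-empty numeric samples.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param correct Multiplicity correction: `"none"` (default) or
#'   `"bonferroni"`.
#' @return A tibble with columns `group`, `mean`, `letters`, ordered by
#'   descending mean; attribute `"p_matrix"` holds the pairwise p-values.
#' @examples
#' set.seed(1)
#' pairwise_letters(list(high = rnorm(10, 5), low = rnorm(10, 0)))
#' @export
pairwise_letters <- function(groups, alpha = 0.05,
                             correct = c("none", "bonferroni")) {
  correct <- match.arg(correct)
  if (!is.list(groups) || length(groups) < 2) {
    abort("Need a named list of at least two groups.")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  k <- length(groups)
  means <- vapply(groups, mean, numeric(1))
  ord <- order(means, decreasing = TRUE)
  groups <- groups[ord]
  means <- means[ord]

  pmat <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- mann_whitney_u(groups[[i]], groups[[j]])$p_value
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  if (correct == "bonferroni") {
    pmat <- pmin(pmat * choose(k, 2), 1)
  }
  sig <- !is.na(pmat) & pmat < alpha

  # insert-and-absorb: start with one letter covering all groups, split
  # on each significant pair, drop letters that become subsets
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      for (s in seq_along(sets)) {
        if (all(c(i, j) %in% sets[[s]])) {
          sets <- c(sets, list(setdiff(sets[[s]], i)), list(setdiff(sets[[s]], j)))
          sets[[s]] <- NA
        }
      }
      sets <- sets[!vapply(sets, function(s) all(is.na(s)), logical(1))]
      keep <- rep(TRUE, length(sets))
      for (s in seq_along(sets)) {
        for (t in seq_along(sets)) {
          if (s != t && keep[t] &&
              all(sets[[s]] %in% sets[[t]]) &&
              (length(sets[[s]]) < length(sets[[t]]) || s > t)) {
            keep[s] <- FALSE
            break
          }
        }
      }
      sets <- sets[keep]
    }
  }
  # order letters by their first (highest-mean) member
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letter_of <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))

  out <- tibble::tibble(group = names(groups), mean = unname(means),
                        letters = letter_of)
  attr(out, "p_matrix") <- pmat
  out
}
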