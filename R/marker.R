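#' Define a diagnostic marker
#'
#' Bundles everything the biotype classifier needs: the two PCR primers
#' that anchor the cytb-16S mitochondrial fragment, the positions of the
#' five diagnostic single-nucleotide sites within the anchored fragment
#' (1-based, counted from the first base after the forward primer), and
#' the two reference genotype patterns. The cotton and cucumber biotypes
#' differ at all five sites, so no genotype can match both.
#'
#' @param forward_primer,reverse_primer Primer sequences, 5'->3'
#'   (DNA/RNA, case-insensitive; U is normalized to T).
#' @param offsets Integer vector of exactly 5 strictly increasing 1-based
#'   positions within the anchored fragment.
#' @param cotton_pattern,cucumber_pattern The 5 diagnostic nucleotides of
#'   each biotype, as a length-5 vector or a 5-character string.
#' @param max_primer_mismatches Mismatches tolerated when locating the
#'   forward primer (default 2); exact matches are preferred when both
#'   occur.
#' @return An object of class `marker_definition`.
#' @examples
#' default_marker()
#' @export
marker_definition <- function(forward_primer, reverse_primer, offsets,
                              cotton_pattern, cucumber_pattern,
                              max_primer_mismatches = 2) {
  norm_pat <- function(p) {
    p <- toupper(paste(p, collapse = ""))
    gsub("U", "T", p)
  }
  fwd <- norm_pat(forward_primer)
  rev <- norm_pat(reverse_primer)
  cot <- norm_pat(cotton_pattern)
  cuc <- norm_pat(cucumber_pattern)
  offsets <- as.integer(offsets)
  if (nchar(fwd) == 0 || nchar(rev) == 0) abort("Primers must be non-empty.")
  if (length(offsets) != 5 || any(diff(offsets) <= 0) || any(offsets < 1)) {
    abort("`offsets` must be 5 strictly increasing positions >= 1.")
  }
  if (nchar(cot) != 5 || nchar(cuc) != 5) {
    abort("Genotype patterns must contain exactly 5 nucleotides.")
  }
  if (any(strsplit(cot, "")[[1]] == strsplit(cuc, "")[[1]])) {
    abort("Cotton and cucumber patterns must differ at all 5 sites.")
  }
  structure(
    list(
      forward_primer = fwd,
      reverse_primer = rev,
      offsets = offsets,
      cotton_pattern = cot,
      cucumber_pattern = cuc,
      max_primer_mismatches = as.integer(max_primer_mismatches)
    ),
    class = "marker_definition"
  )
}

#' @export
print.marker_definition <- function(x, ...) {
  cat("<marker_definition>\n")
  cat("  forward primer :", x$forward_primer, "\n")
  cat("  reverse primer :", x$reverse_primer, "\n")
  cat("  diagnostic sites (1-based in anchored fragment):",
      paste(x$offsets, collapse = ", "), "\n")
  cat("  cotton pattern  :", paste(strsplit(x$cotton_pattern, "")[[1]],
                                   collapse = ", "), "\n")
  cat("  cucumber pattern:", paste(strsplit(x$cucumber_pattern, "")[[1]],
                                   collapse = ", "), "\n")
  cat("  max primer mismatches:", x$max_primer_mismatches, "\n")
  invisible(x)
}

#' Read or write a marker definition config
#'
#' Marker definitions are stored as YAML with keys `forward_primer`,
#' `reverse_primer`, `offsets`, `cotton_pattern`, `cucumber_pattern`,
#' `max_primer_mismatches`.
#'
#' @param path Path to the YAML file.
#' @return [read_marker()] returns a [marker_definition()];
#'   [write_marker()] returns `path` invisibly.
#' @export
read_marker <- function(path) {
  cfg <- yaml::read_yaml(path)
  needed <- c("forward_primer", "reverse_primer", "offsets",
              "cotton_pattern", "cucumber_pattern")
  missing <- setdiff(needed, names(cfg))
  if (length(missing) > 0) {
    abort(sprintf(
      "Marker config %s is missing key(s): %s.",
      path, paste(missing, collapse = ", ")
    ))
  }
  marker_definition(
    forward_primer = cfg$forward_primer,
    reverse_primer = cfg$reverse_primer,
    offsets = cfg$offsets,
    cotton_pattern = cfg$cotton_pattern,
    cucumber_pattern = cfg$cucumber_pattern,
    max_primer_mismatches = cfg$max_primer_mismatches %||% 2
  )
}

#' @rdname read_marker
#' @param marker A [marker_definition()] to serialize.
#' @export
write_marker <- function(marker, path) {
  yaml::write_yaml(
    list(
      forward_primer = marker$forward_primer,
      reverse_primer = marker$reverse_primer,
      offsets = as.integer(marker$offsets),
      cotton_pattern = marker$cotton_pattern,
      cucumber_pattern = marker$cucumber_pattern,
      max_primer_mismatches = as.integer(marker$max_primer_mismatches)
    ),
    path
  )
  invisible(path)
}

#' The packaged cytb-16S biotype marker
#'
#' The marker definition shipped with the package: the published CytbF /
#' 16SR primer pair, the cotton-biotype pattern T,A,A,T,T and the
#' cucumber-biotype pattern C,G,G,C,C. The five diagnostic coordinates
#' of the real amplicon are not public, so the packaged offsets are an
#' arbitrary documented choice used by the synthetic reference fragments
#' in `inst/extdata/`; analyses of real amplicons must supply a marker
#' config with the true offsets.
#'
#' @return A [marker_definition()].
#' @export
default_marker <- function() {
  marker_definition(
    forward_primer = "TACCATGAGGACAAATATCATTTTGA", # CytbF
    reverse_primer = "AAGGGACGATAAGACCCTATAAAAC",  # 16SR
    offsets = c(28L, 41L, 55L, 68L, 82L),
    cotton_pattern = "TAATT",
    cucumber_pattern = "CGGCC",
    max_primer_mismatches = 2
  )
}
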