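norm_seq <- function(x) {
  x <- toupper(as.character(x))
  gsub("U", "T", x)
}

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

check_alphabet <- function(seq, id = "sequence") {
  chars <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(chars, IUPAC_CODES)
  if (length(bad) > 0) {
    abort(sprintf(
      "Record '%s' contains non-IUPAC character(s): %s.",
      id, paste(bad, collapse = ", ")
    ))
  }
  invisible(seq)
}

# best forward-primer hit in one strand: fewest mismatches, then leftmost
best_primer_hit <- function(seq, primer, max_mismatch) {
  subject <- Biostrings::DNAString(seq)
  for (mm in 0:max_mismatch) {
    hits <- Biostrings::matchPattern(
      Biostrings::DNAString(primer), subject,
      max.mismatch = mm, with.indels = FALSE
    )
    if (length(hits) > 0) {
      return(list(start = Biostrings::start(hits)[1],
                  end = Biostrings::end(hits)[1],
                  mismatches = mm))
    }
  }
  NULL
}

#' Anchor the marker fragment in a sequence
#'
#' Locates the forward primer (tolerating up to
#' `marker$max_primer_mismatches` substitutions, exact matches
#' preferred) on the given strand and, failing that, on the reverse
#' complement. The anchored fragment is the subsequence from the first
#' base after the forward-primer match to the end of the (possibly
#' reverse-complemented) sequence; diagnostic offsets are counted within
#' it. A sequence in which the primer is not found on either strand is
#' flagged not-amplifiable — the in-silico analogue of a diagnostic PCR
#' that fails on a divergent aphid species.
#'
#' @param sequence A nucleotide string (or `DNAString`); IUPAC alphabet,
#'   case-insensitive, U normalized to T.
#' @param marker A [marker_definition()].
#' @return A list: `amplifiable` (logical), and when amplifiable
#'   `fragment` (string), `orientation` (`"forward"` or
#'   `"reverse_complement"`), `fragment_start` (1-based position of the
#'   fragment's first base in the oriented sequence) and `mismatches`;
#'   otherwise a `reason` string.
#' @export
locate_marker <- function(sequence, marker) {
  seq <- norm_seq(sequence)
  check_alphabet(seq)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))
  )
  strands <- list(forward = seq, reverse_complement = rc)
  best <- NULL
  for (ori in names(strands)) {
    hit <- best_primer_hit(strands[[ori]], marker$forward_primer,
                           marker$max_primer_mismatches)
    if (!is.null(hit) &&
        (is.null(best) || hit$mismatches < best$mismatches)) {
      best <- c(hit, list(orientation = ori, oriented = strands[[ori]]))
      if (hit$mismatches == 0) break # exact match preferred, forward first
    }
  }
  if (is.null(best)) {
    return(list(
      amplifiable = FALSE,
      reason = sprintf(
        "forward primer not found within %d mismatches on either strand",
        marker$max_primer_mismatches
      )
    ))
  }
  list(
    amplifiable = TRUE,
    fragment = substr(best$oriented, best$end + 1, nchar(best$oriented)),
    orientation = best$orientation,
    fragment_start = best$end + 1,
    mismatches = best$mismatches
  )
}

#' Extract the five diagnostic nucleotides
#'
#' Reads the bases at the marker's diagnostic offsets (1-based within
#' the anchored fragment), uppercased with U normalized to T.
#'
#' @param fragment Anchored fragment string from [locate_marker()].
#' @param marker A [marker_definition()].
#' @return A 5-character genotype string (e.g. `"TAATT"`).
#' @export
extract_genotype <- function(fragment, marker) {
  fragment <- norm_seq(fragment)
  if (nchar(fragment) < max(marker$offsets)) {
    abort(sprintf(
      "Fragment of length %d is truncated before diagnostic site %d.",
      nchar(fragment), max(marker$offsets)
    ))
  }
  paste(strsplit(fragment, "")[[1]][marker$offsets], collapse = "")
}

#' Classify a 5-site genotype
#'
#' All five bases matching the cotton pattern call the cotton biotype;
#' all five matching the cucumber pattern call the cucumber biotype. Any
#' IUPAC ambiguity code at a diagnostic site yields `ambiguous` (the
#' base call cannot be trusted), and every other combination — including
#' mixtures of the two patterns — is treated as another aphid species,
#' since a divergent mitochondrial background is the usual source of
#' off-pattern sites.
#'
#' @param genotype 5 observed bases (string or character vector).
#' @param marker A [marker_definition()].
#' @return One of `"cotton"`, `"cucumber"`, `"ambiguous"`,
#'   `"other_species"`.
#' @examples
#' classify_biotype("TAATT", default_marker()) # cotton
#' classify_biotype("CGGCC", default_marker()) # cucumber
#' @export
classify_biotype <- function(genotype, marker) {
  g <- norm_seq(paste(genotype, collapse = ""))
  if (nchar(g) != 5) abort("Genotype must contain exactly 5 bases.")
  bases <- strsplit(g, "")[[1]]
  if (any(!bases %in% c("A", "C", "G", "T"))) {
    return("ambiguous")
  }
  if (g == marker$cotton_pattern) {
    return("cotton")
  }
  if (g == marker$cucumber_pattern) {
    return("cucumber")
  }
  "other_species"
}

#' Classify every sequence in a batch
#'
#' Runs the full per-sequence pipeline — primer anchoring, genotype
#' extraction, pattern matching — over a FASTA file or `DNAStringSet`.
#' Results depend only on each sequence, so the output order mirrors the
#' input and permuting the input permutes the calls identically. A
#' fragment too short to cover all diagnostic sites is called
#' `other_species` with a truncation reason.
#'
#' @param records Path to a FASTA file, a named character vector, or a
#'   `Biostrings::DNAStringSet`.
#' @param marker A [marker_definition()].
#' @param metadata Optional tibble/data.frame with an `id` column (e.g.
#'   host, collection_time, morph) joined onto the calls.
#' @return A tibble with columns `id`, `call`, `genotype`, `orientation`,
#'   `reason` (plus any metadata columns). `genotype` is `NA` for
#'   non-amplifiable or truncated records.
#' @export
classify_batch <- function(records, marker, metadata = NULL) {
  seqs <- as_dna_characters(records)
  if (length(seqs) == 0) {
    out <- tibble::tibble(
      id = character(), call = character(), genotype = character(),
      orientation = character(), reason = character()
    )
    return(join_metadata(out, metadata))
  }
  rows <- lapply(seq_along(seqs), function(i) {
    id <- names(seqs)[i]
    loc <- locate_marker(seqs[[i]], marker)
    if (!loc$amplifiable) {
      return(tibble::tibble(
        id = id, call = "other_species", genotype = NA_character_,
        orientation = NA_character_, reason = loc$reason
      ))
    }
    if (nchar(loc$fragment) < max(marker$offsets)) {
      return(tibble::tibble(
        id = id, call = "other_species", genotype = NA_character_,
        orientation = loc$orientation,
        reason = sprintf("fragment truncated at %d bases", nchar(loc$fragment))
      ))
    }
    g <- extract_genotype(loc$fragment, marker)
    call <- classify_biotype(g, marker)
    tibble::tibble(
      id = id, call = call, genotype = g, orientation = loc$orientation,
      reason = switch(call,
        cotton = "matches cotton pattern",
        cucumber = "matches cucumber pattern",
        ambiguous = "ambiguity code at a diagnostic site",
        other_species = "genotype matches neither biotype pattern"
      )
    )
  })
  out <- dplyr::bind_rows(rows)
  join_metadata(out, metadata)
}

as_dna_characters <- function(records) {
  if (is.character(records) && length(records) == 0) {
    return(character())
  }
  if (is.character(records) && length(records) == 1 && file.exists(records)) {
    records <- tryCatch(
      Biostrings::readDNAStringSet(records),
      error = function(e) {
        abort(sprintf("Malformed FASTA '%s': %s", records, conditionMessage(e)))
      }
    )
  }
  if (is(records, "DNAStringSet") || is(records, "RNAStringSet")) {
    seqs <- as.character(records)
    # FASTA headers may carry descriptions; the id is the first word
    names(seqs) <- sub("\\s.*$", "", names(records))
  } else if (is.character(records)) {
    seqs <- records
    if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  } else {
    abort("`records` must be a FASTA path, character vector, or DNAStringSet.")
  }
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0) {
    abort(sprintf("Record %d ('%s') has an empty sequence.",
                  empty[1], names(seqs)[empty[1]]))
  }
  seqs
}

join_metadata <- function(calls, metadata) {
  if (is.null(metadata)) {
    return(calls)
  }
  metadata <- tibble::as_tibble(metadata)
  if (!"id" %in% names(metadata)) {
    abort("Metadata must contain an `id` column.")
  }
  missing <- setdiff(calls$id, metadata$id)
  if (length(missing) > 0) {
    abort(sprintf(
      "Metadata missing for record(s): %s.",
      paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  dplyr::left_join(calls, metadata, by = "id")
}

#' Read a sequence metadata sidecar CSV
#'
#' Columns `id,host,collection_time,morph`; extra columns are kept.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_sequence_metadata <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!"id" %in% names(df)) {
    abort(sprintf("Metadata CSV %s must contain an `id` column.", path))
  }
  df
}
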