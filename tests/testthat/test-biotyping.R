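marker <- default_marker()

test_that("marker definitions enforce their structural invariants", {
  expect_error(
    marker_definition("ACGT", "ACGT", c(1, 2, 3, 4), "TAATT", "CGGCC"),
    "5 strictly increasing"
  )
  expect_error(
    marker_definition("ACGT", "ACGT", c(1, 2, 3, 4, 5), "TAATT", "CGATC"),
    "differ at all 5 sites"
  )
  expect_error(
    marker_definition("", "ACGT", c(1, 2, 3, 4, 5), "TAATT", "CGGCC"),
    "non-empty"
  )
  # case and RNA input are normalized
  mk <- marker_definition("acgu", "ggcc", c(2, 4, 6, 8, 10), "uaauu", "cggcc")
  expect_equal(mk$forward_primer, "ACGT")
  expect_equal(mk$cotton_pattern, "TAATT")
})

test_that("marker configs round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_marker(marker, path)
  back <- read_marker(path)
  expect_equal(back, marker)
})

test_that("the packaged synthetic references carry the published patterns", {
  fasta <- system.file("extdata", "synthetic_reference_fragments.fasta",
                       package = "aphidbiotype")
  calls <- classify_batch(fasta, marker)
  expect_equal(calls$call, c("cotton", "cucumber"))
  expect_equal(calls$genotype, c("TAATT", "CGGCC"))
})

test_that("primer anchoring is strand-aware and mismatch-tolerant", {
  set.seed(21)
  sim <- simulate_marker_sequences(
    sequence_sim_config(n_cotton = 1, n_cucumber = 0, n_other = 0, seed = 21),
    marker
  )
  seq_fwd <- as.character(sim$sequences)[[1]]

  loc <- locate_marker(seq_fwd, marker)
  expect_true(loc$amplifiable)
  expect_equal(loc$orientation, "forward")
  expect_equal(loc$fragment_start, nchar(marker$forward_primer) + 1)

  # the reverse complement anchors to the identical fragment
  loc_rc <- locate_marker(reverse_complement_chr(seq_fwd), marker)
  expect_true(loc_rc$amplifiable)
  expect_equal(loc_rc$orientation, "reverse_complement")
  expect_equal(loc_rc$fragment, loc$fragment)

  # two substitutions inside the primer are tolerated, three are not
  mutate_at <- function(s, pos) {
    subs <- c(A = "C", C = "A", G = "T", T = "G")
    chars <- strsplit(s, "")[[1]]
    chars[pos] <- subs[chars[pos]]
    paste(chars, collapse = "")
  }
  expect_true(locate_marker(mutate_at(seq_fwd, c(3, 9)), marker)$amplifiable)
  loc3 <- locate_marker(mutate_at(seq_fwd, c(3, 9, 15)), marker)
  expect_false(loc3$amplifiable)
  expect_match(loc3$reason, "primer not found")
})

test_that("genotype extraction reads the diagnostic offsets", {
  frag <- strsplit(paste(rep("G", 100), collapse = ""), "")[[1]]
  frag[marker$offsets] <- c("T", "A", "A", "T", "T")
  expect_equal(extract_genotype(paste(frag, collapse = ""), marker), "TAATT")
  # lowercase RNA input is normalized before reading
  expect_equal(
    extract_genotype(tolower(gsub("T", "U", paste(frag, collapse = ""))),
                     marker),
    "TAATT"
  )
  expect_error(extract_genotype("ACGTACGT", marker), "truncated")
})

test_that("genotypes classify to biotype, other species, or ambiguous", {
  expect_equal(classify_biotype("TAATT", marker), "cotton")
  expect_equal(classify_biotype("CGGCC", marker), "cucumber")
  # one off-pattern site: another species, never the wrong biotype
  expect_equal(classify_biotype("TGATT", marker), "other_species")
  # mixture of the two patterns is not a biotype either
  expect_equal(classify_biotype("TGGCC", marker), "other_species")
  # IUPAC ambiguity code at a diagnostic site
  expect_equal(classify_biotype("NAATT", marker), "ambiguous")
  expect_equal(classify_biotype("TARTT", marker), "ambiguous")
  expect_error(classify_biotype("TAAT", marker), "exactly 5")
})

test_that("batch classification recovers simulated ground truth", {
  cfg <- sequence_sim_config(n_cotton = 20, n_cucumber = 10, n_other = 1,
                             seed = 33)
  sim <- simulate_marker_sequences(cfg, marker)
  calls <- classify_batch(sim$sequences, marker)
  expect_equal(nrow(calls), 31)
  expect_equal(calls$call, sim$truth$true_class)
  expect_equal(sum(calls$call == "cotton"), 20)
  expect_equal(sum(calls$call == "cucumber"), 10)
  expect_equal(sum(calls$call == "other_species"), 1)
  # reported orientation matches how each record was emitted
  expect_equal(
    calls$orientation[calls$call != "other_species"],
    sim$truth$emitted_orientation[sim$truth$true_class != "other_species"]
  )
})

test_that("batch results are order-independent and empty input is empty", {
  cfg <- sequence_sim_config(n_cotton = 4, n_cucumber = 4, n_other = 2,
                             seed = 5)
  sim <- simulate_marker_sequences(cfg, marker)
  calls <- classify_batch(sim$sequences, marker)
  perm <- sample(length(sim$sequences))
  calls_perm <- classify_batch(sim$sequences[perm], marker)
  expect_equal(calls_perm, calls[perm, ])

  empty <- classify_batch(character(), marker)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("id", "call", "genotype", "orientation", "reason"))
})

test_that("diagnostic-site noise never produces the wrong biotype", {
  set.seed(9)
  cfg <- sequence_sim_config(n_cotton = 30, n_cucumber = 0, n_other = 0,
                             seed = 9)
  sim <- simulate_marker_sequences(cfg, marker)
  seqs <- as.character(sim$sequences)
  # corrupt one diagnostic site in each forward-emitted cotton fragment
  fwd <- which(sim$truth$emitted_orientation == "forward")
  corrupted <- vapply(seqs[fwd], function(s) {
    pos <- nchar(marker$forward_primer) + sample(marker$offsets, 1)
    chars <- strsplit(s, "")[[1]]
    chars[pos] <- setdiff(c("A", "C", "G", "T"), chars[pos])[1]
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  calls <- classify_batch(corrupted, marker)
  expect_true(all(calls$call %in% c("other_species", "ambiguous")))
  expect_false(any(calls$call == "cucumber"))
})

test_that("metadata joins validate ids and malformed FASTA is reported", {
  cfg <- sequence_sim_config(n_cotton = 2, n_cucumber = 0, n_other = 0,
                             seed = 2)
  sim <- simulate_marker_sequences(cfg, marker)
  meta <- tibble::tibble(id = sim$truth$id[1], host = "cotton")
  expect_error(classify_batch(sim$sequences, marker, metadata = meta),
               "Metadata missing")
  ok <- classify_batch(
    sim$sequences, marker,
    metadata = tibble::tibble(id = sim$truth$id, host = "cotton")
  )
  expect_equal(ok$host, c("cotton", "cotton"))
})
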