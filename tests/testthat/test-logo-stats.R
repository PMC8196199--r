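test_that("information content hits its analytic limits", {
  # perfectly conserved ungapped column: R = log2(20), c = R
  al <- endgap_alignment(stats::setNames(rep("W", 5), paste0("s", 1:5)))
  logo <- build_logo(al, "t")
  expect_equal(logo$columns$information, log2(20), tolerance = 1e-9)
  expect_equal(logo$columns$conservation, log2(20), tolerance = 1e-9)
  expect_equal(logo$columns$occupancy, 1)

  # 20 sequences, one of each amino acid: R = 0
  al20 <- endgap_alignment(stats::setNames(AA20, paste0("s", 1:20)))
  logo20 <- build_logo(al20, "t")
  expect_equal(logo20$columns$information, 0, tolerance = 1e-9)
})

test_that("occupancy weights conservation for half-gapped columns", {
  # column 2: 'A' in half the sequences, end gap in the other half
  al <- endgap_alignment(c(s1 = "AA", s2 = "AA", s3 = "A", s4 = "A"))
  logo <- build_logo(al, "t")
  expect_equal(logo$columns$occupancy[2], 0.5)
  expect_equal(logo$columns$information[2], log2(20), tolerance = 1e-9)
  expect_equal(logo$columns$conservation[2], 0.5 * log2(20),
               tolerance = 1e-9)
})

test_that("'X' counts toward occupancy but toward no amino acid", {
  al <- endgap_alignment(c(s1 = "W", s2 = "W", s3 = "X", s4 = "X"))
  logo <- build_logo(al, "t")
  expect_equal(logo$columns$occupancy, 1)
  expect_equal(sum(logo$fractions[, 1]), 0.5)  # only the W fraction
  # q = p^W / p = 0.5: R = log2 20 + 0.5 log2 0.5
  expect_equal(logo$columns$information, log2(20) - 0.5, tolerance = 1e-9)
})

test_that("average information is the occupancy-weighted column mean", {
  logo <- fake_logo(p = c(1, 0.5), R = c(4, 2))
  expect_equal(average_information(logo), 10 / 3, tolerance = 1e-12)
  # invariant under column reordering
  logo_rev <- fake_logo(p = c(0.5, 1), R = c(2, 4))
  expect_equal(average_information(logo_rev), 10 / 3, tolerance = 1e-12)
  # constant columns: R_avg equals the common value
  expect_equal(average_information(fake_logo(p = c(1, 1), R = c(3, 3))), 3)
})

test_that("reference selection takes the leftmost maximum, strict 2-bit rule", {
  ref <- select_reference(fake_logo(p = c(1, 1, 1), R = c(1, 3, 3)))
  expect_identical(ref$index, 2L)
  expect_true(ref$eligible)
  # max conservation exactly 2 bits is NOT eligible
  ref2 <- select_reference(fake_logo(p = c(1, 0.5), R = c(2, 1)))
  expect_identical(ref2$index, 1L)
  expect_false(ref2$eligible)
  expect_error(build_logo(structure(list(sequences = character(0)),
                                    class = "endgap_alignment")),
               "empty")
})

test_that("logo statistics satisfy their bounds on random alignments", {
  set.seed(5)
  for (rep in 1:15) {
    n <- sample(3:10, 1)
    seqs <- stats::setNames(
      vapply(seq_len(n), function(i) random_protein(sample(4:9, 1)), ""),
      paste0("s", seq_len(n)))
    logo <- build_logo(align_nogap(seqs), "t")
    cols <- logo$columns
    expect_true(all(cols$information >= -1e-12 &
                    cols$information <= log2(20) + 1e-12))
    expect_true(all(cols$conservation <= cols$information + 1e-12))
    full <- cols$occupancy == 1
    expect_equal(cols$conservation[full], cols$information[full])
    expect_true(all(cols$occupancy > 0))  # no all-gap columns
    expect_gte(logo$r_avg, min(cols$information) - 1e-12)
    expect_lte(logo$r_avg, max(cols$information) + 1e-12)
    # duplicating every sequence changes nothing
    dup <- endgap_alignment(stats::setNames(rep(logo_seqs <- seqs, 2),
                                            paste0("s", seq_len(2 * n))),
                            rep(align_nogap(seqs)$offsets, 2))
    logo2 <- build_logo(dup, "t")
    expect_equal(logo2$columns$occupancy, cols$occupancy)
    expect_equal(logo2$columns$information, cols$information)
    expect_equal(logo2$r_avg, logo$r_avg)
  }
})

test_that("a planted consensus position is recovered as the reference", {
  hits <- 0L
  for (rep in 1:20) {
    spec <- one_class_spec(
      50, seed = 1000 + rep,
      length_dist = length_constant(10),
      consensus = list(position = 5, aa = "W", prob = 0.9))
    set <- generate_annotation_set(spec)
    al <- align_nogap(class_sequences(set, "C"))
    logo <- build_logo(al, "C")
    ref <- select_reference(logo)
    # offsets are mostly 0, so the planted position sits at column 5
    if (ref$index == 5L && ref$eligible) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("logo TSV export holds one row per column with fractions", {
  al <- align_nogap(c(a = "AWA", b = "AWA", c = "WA"))
  logo <- build_logo(al, "C")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_logo_tsv(logo, path)
  df <- utils::read.delim(path)
  expect_identical(nrow(df), nrow(logo$columns))
  expect_true(all(c("index", "occupancy", "information", "conservation",
                    "W") %in% names(df)))
})
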