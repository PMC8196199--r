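test_that("trivial alignments behave as forced by the objective", {
  al <- align_nogap(c(a = "ACD"))
  expect_identical(al$offsets, 0L)
  expect_identical(al$width, 3L)
  expect_identical(sop_score(al), 0)  # no pairs

  al2 <- align_nogap(c(a = "ACDE", b = "ACDE"))
  expect_identical(al2$offsets, c(0L, 0L))
  expect_identical(al2$width, 4L)
})

test_that("sum-of-pairs score matches hand-computed BLOSUM62 values", {
  # two identical ACDE sequences: diagonal entries A+C+D+E
  al <- endgap_alignment(c(a = "ACDE", b = "ACDE"))
  expect_identical(sop_score(al),
                   sum(B62[c("A", "C", "D", "E")]) + 0)
  # shifting one AA by a column trades a match for two end-gap columns
  stay <- endgap_alignment(c(a = "AA", b = "AA"), c(0L, 0L))
  slip <- endgap_alignment(c(a = "AA", b = "AA"), c(0L, 1L))
  expect_identical(sop_score(stay), 2 * B62[["A"]] + 0)
  expect_identical(sop_score(slip), B62[["A"]] - 2 * 10)
  expect_lt(sop_score(slip), sop_score(stay))
  # 'X' is scored 0 against everything but still counts as occupancy
  xal <- endgap_alignment(c(a = "AXA", b = "AWA"))
  expect_identical(sop_score(xal), 2 * B62[["A"]] + 0)
})

test_that("aligner pins the conserved tryptophan and matches the oracle", {
  al <- align_nogap(c(a = "AAWAA", b = "WAA"))
  chars <- as.character(al)
  wcol_a <- regexpr("W", chars[["a"]])
  wcol_b <- regexpr("W", chars[["b"]])
  expect_identical(wcol_a, wcol_b)
  expect_identical(sop_score(al),
                   sop_score(oracle_align(c(a = "AAWAA", b = "WAA"))))
})

test_that("input validation rejects empty and non-amino-acid input", {
  expect_error(align_nogap(character(0)), "at least one")
  expect_error(align_nogap(c(a = "")), "empty sequence")
  expect_error(align_nogap(c(a = "AB1")), "invalid residue")
  expect_error(oracle_align(stats::setNames(rep("ACDEFGHIKLM", 2),
                                            c("a", "b"))),
               "too large")
})

test_that("every alignment output satisfies the end-gap invariants", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(2:7, 1)
    seqs <- stats::setNames(
      vapply(seq_len(n), function(i) random_protein(sample(3:12, 1)), ""),
      paste0("s", seq_len(n)))
    al <- align_nogap(seqs)
    expect_identical(min(al$offsets), 0L)
    expect_identical(al$width, max(al$offsets + nchar(al$sequences)))
    chars <- as.character(al)
    expect_true(all(grepl("^-*[A-Z]+-*$", chars)))  # contiguous block
    # heuristic is at least as good as the unshifted stacking
    trivial <- endgap_alignment(seqs, 0L)
    expect_gte(sop_score(al), sop_score(trivial))
  }
})

test_that("optimal score is invariant under input permutation", {
  set.seed(77)
  for (rep in 1:10) {
    seqs <- stats::setNames(
      vapply(1:3, function(i) random_protein(sample(3:8, 1)), ""),
      c("a", "b", "c"))
    s1 <- sop_score(align_nogap(seqs))
    s2 <- sop_score(align_nogap(seqs[c(3, 1, 2)]))
    expect_equal(s1, s2, tolerance = 1e-12)
  }
})

test_that("aligner reaches the exhaustive optimum on random tiny instances", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(1:4, 1)
    seqs <- stats::setNames(
      vapply(seq_len(n), function(i) random_protein(sample(1:8, 1)), ""),
      paste0("s", seq_len(n)))
    expect_equal(sop_score(align_nogap(seqs)),
                 sop_score(oracle_align(seqs)), tolerance = 1e-9)
  }
})

test_that("equal-length sequences with a planted column align unshifted", {
  set.seed(13)
  for (rep in 1:10) {
    seqs <- vapply(1:8, function(i) {
      s <- sample(AA20, 9, replace = TRUE)
      s[5] <- "W"
      paste(s, collapse = "")
    }, "")
    names(seqs) <- paste0("s", 1:8)
    al <- align_nogap(seqs)
    expect_true(all(al$offsets == 0L))
  }
})

test_that("aligned FASTA round-trips and rejects internal gaps", {
  al <- align_nogap(c(a = "AAWAA", b = "WAA", c = "AWA"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(al, path)
  al2 <- read_alignment_fasta(path)
  expect_identical(al2$offsets, al$offsets)
  expect_identical(al2$sequences, al$sequences)
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "AA-AA", ">y", "AAAAA"), bad)
  expect_error(read_alignment_fasta(bad), "internal gaps")
})

test_that("substitution matrices read from NCBI text format are usable", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# toy identity-like matrix",
               paste(c("", AA20), collapse = " "),
               vapply(seq_along(AA20), function(i) {
                 row <- rep(-1L, 20)
                 row[i] <- 5L
                 paste(c(AA20[i], row), collapse = " ")
               }, "")), path)
  m <- read_substitution_matrix(path)
  expect_identical(dim(m), c(20L, 20L))
  p <- alignment_params(matrix = m, gap_penalty = 2)
  expect_identical(p$matrix["A", "A"], 5)
  expect_identical(p$matrix["X", "W"], 0)
  al <- endgap_alignment(c(a = "AC", b = "AC"))
  expect_identical(sop_score(al, p), 10)
})
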