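test_that("SSE construction enforces range, sequence and metric invariants", {
  s <- sse_annotation("I", "helix", 284, 316,
                      paste(rep("A", 33), collapse = ""))
  expect_s3_class(s, "sse_annotation")
  expect_error(sse_annotation("B''", "helix", 114, 112),
               "invalid residue range")
  expect_error(sse_annotation("C", "helix", 117, 131, "WDEM"),
               "does not match residue range")
  expect_error(sse_annotation("C", "helix", 1, 3, "A1B"), "invalid residue")
  expect_error(sse_annotation("C", "helix", 1, 3, "AAA", metric = -1),
               "non-negative")
})

test_that("sse_length is the inclusive residue count", {
  expect_identical(sse_length(sse_annotation("I", "helix", 284, 316)), 33L)
  expect_identical(sse_length(sse_annotation("B''", "helix", 112, 114)), 3L)
  expect_identical(sse_length(sse_annotation("b6-1", "strand", 362, 362)), 1L)
})

test_that("domain and set constructors reject duplicate labels and ids", {
  expect_error(domain_record("d1", list(
    sse_annotation("C", "helix", 1, 3),
    sse_annotation("C", "helix", 5, 7))), "duplicated SSE labels")
  expect_error(annotation_set(list(domain_record("d1"), domain_record("d1"))),
               "duplicated domain ids")
  expect_error(domain_record(""), "nonempty")
})

test_that("labels outside class_order are kept and flagged unclassified", {
  set <- annotation_set(list(
    domain_record("d1", list(sse_annotation("Zx", "helix", 1, 3)))),
    class_order = "C")
  expect_identical(set$unclassified, "Zx")
  expect_length(class_sequences(set, "Zx"), 0L)  # present but no sequence
})

test_that("annotation JSON round-trips through write and load", {
  set <- tiny_set()
  dir <- withr::local_tempdir()
  paths <- write_annotation_set(set, dir)
  expect_length(paths, 3L)
  set2 <- load_annotation_set(paths, class_order = set$class_order)
  expect_identical(names(set2$domains), names(set$domains))
  for (id in names(set$domains)) {
    a <- set$domains[[id]]$sses
    b <- set2$domains[[id]]$sses
    expect_identical(names(a), names(b))
    for (lab in names(a)) {
      expect_identical(a[[lab]][c("label", "sse_type", "start", "end",
                                  "sequence")],
                       b[[lab]][c("label", "sse_type", "start", "end",
                                  "sequence")])
      expect_identical(sse_length(b[[lab]]), nchar(b[[lab]]$sequence))
    }
  }
})

test_that("loader reports malformed files and violated invariants by name", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "broken.sses.json")
  writeLines("{not json", bad)
  expect_error(load_annotation_set(bad), "malformed JSON.*broken")
  mism <- file.path(dir, "mism.sses.json")
  writeLines(
    '{"domain":"mismA","sses":[{"label":"C","type":"H","start":114,"end":112,"sequence":"AAA"}]}',
    mism)
  expect_error(load_annotation_set(mism), "invalid residue range")
  expect_identical(length(load_annotation_set(character(0))), 0L)
})

test_that("metadata joins by domain_id", {
  set <- tiny_set()
  dir <- withr::local_tempdir()
  paths <- write_annotation_set(set, dir)
  meta_path <- file.path(dir, "meta.tsv")
  utils::write.table(
    data.frame(domain_id = c("d1A", "d2A"), pdb = c("d1", "d2"),
               chain = "A", uniprot_id = c("P001", "P002"),
               superkingdom = c("Bacteria", "Eukaryota"),
               quality = c(42.46, 30)),
    meta_path, sep = "\t", row.names = FALSE, quote = FALSE)
  loaded <- load_annotation_set(paths, read_domain_metadata(meta_path))
  expect_identical(loaded$domains[["d1A"]]$superkingdom, "Bacteria")
  expect_identical(loaded$domains[["d2A"]]$quality, 30)
  expect_null(loaded$domains[["d3A"]]$uniprot_id)
})

test_that("class_sequences returns per-domain sequences in set order", {
  set <- tiny_set()
  seqs <- class_sequences(set, "I")
  expect_identical(names(seqs), c("d1A", "d2A"))
  expect_length(class_sequences(set, "b5-1"), 1L)
  expect_error(class_sequences(set, "nope"), "unknown SSE class")
})

test_that("class FASTA round-trips with 60-column wrapping", {
  set.seed(11)
  seqs <- stats::setNames(vapply(1:60, function(i) random_protein(80), ""),
                          sprintf("dom%02d", 1:60))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_class_fasta(seqs, path)
  lines <- readLines(path)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  expect_identical(read_class_fasta(path), seqs)
  expect_error(write_class_fasta(c(a = ""), path), "empty sequence")
  expect_warning(write_class_fasta(character(0), path), "empty FASTA")
})
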