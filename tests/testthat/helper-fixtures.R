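# Shared fixture builders: everything is constructed in code, no stored
# data files.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# canonical BLOSUM62 diagonal entries used in hand-computed scores
B62 <- c(A = 4, C = 9, D = 6, E = 5, W = 11)

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# a tiny three-domain set: helix C present in all, helix I in two,
# strand b5-1 in one
tiny_set <- function() {
  annotation_set(list(
    domain_record("d1A", list(
      sse_annotation("C", "helix", 117, 131, "WDEMMPRHASLLQAV"),
      sse_annotation("I", "helix", 284, 316,
                     paste(rep("A", 33), collapse = "")),
      sse_annotation("b5-1", "strand", 274, 274, "V"))),
    domain_record("d2A", list(
      sse_annotation("C", "helix", 110, 124, "WDELMPRHATLLQGV"),
      sse_annotation("I", "helix", 280, 312,
                     paste(rep("L", 33), collapse = "")))),
    domain_record("d3A", list(
      sse_annotation("C", "helix", 117, 131, "WDEMMPRHASLLQAV")))),
    class_order = c("C", "I", "b5-1"))
}

# minimal one-class family spec for simulation-heavy tests
one_class_spec <- function(n_domains, seed, occurrence_prob = 1,
                           length_dist = length_constant(10),
                           consensus = NULL) {
  family_spec(n_domains,
              list(class_spec("C", occurrence_prob = occurrence_prob,
                              length_dist = length_dist,
                              consensus = consensus)),
              seed = seed)
}

# fabricate an sse_logo from (occupancy, information) pairs, for testing
# statistics that consume logos
fake_logo <- function(p, R, label = "Z") {
  cols <- data.frame(index = seq_along(p), occupancy = p,
                     information = R, conservation = p * R)
  ref <- which.max(cols$conservation)
  structure(list(sse_label = label, columns = cols,
                 fractions = NULL, n_sequences = 10L,
                 r_avg = sum(p * R) / sum(p), reference_index = ref,
                 eligible = cols$conservation[ref] > 2),
            class = "sse_logo")
}
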