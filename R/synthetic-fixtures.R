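# Seeded generator of synthetic annotation sets with known ground truth.
#
# Emulates the statistical structure of a real protein family's SSE
# anatomy: per-class Bernoulli occurrence, per-class length distributions
# (constant, discretized normal, or two-point bimodal like the 10/15
# bimodality of a helix split between taxa), and per-class sequences
# drawn i.i.d. from a background distribution except for one planted
# high-consensus reference position. Every (domain, class) pair draws
# from its own counter-derived substream, so adding a class never shifts
# another class's draws.

#' Specify one synthetic SSE class
#'
#' @param label class label.
#' @param occurrence_prob probability in `[0, 1]` that a domain carries
#'   the class.
#' @param length_dist one of `length_constant()`, `length_dnorm()`,
#'   `length_bimodal()`.
#' @param consensus optional list `(position, aa, prob)`: the planted
#'   reference position (1-based within the SSE; must not exceed the
#'   minimum possible length), its consensus amino acid, and the
#'   probability of emitting it there.
#' @param sse_type `"helix"` or `"strand"`.
#' @return A `class_spec` list.
#' @export
class_spec <- function(label, occurrence_prob = 1, length_dist =
                         length_constant(10), consensus = NULL,
                       sse_type = "helix") {
  stopifnot(occurrence_prob >= 0, occurrence_prob <= 1)
  if (!is.null(consensus)) {
    stopifnot(all(c("position", "aa", "prob") %in% names(consensus)),
              consensus$prob >= 0, consensus$prob <= 1,
              consensus$aa %in% AMINO_ACIDS)
    if (consensus$position > length_dist$min_length)
      stop(sprintf(
        "class '%s': consensus position %d exceeds minimum length %d",
        label, consensus$position, length_dist$min_length), call. = FALSE)
  }
  structure(list(label = label, occurrence_prob = occurrence_prob,
                 length_dist = length_dist, consensus = consensus,
                 sse_type = match.arg(sse_type, c("helix", "strand"))),
            class = "class_spec")
}

#' Length distributions for synthetic SSE classes
#'
#' `length_constant(l)` always draws `l`; `length_dnorm(mean, sd)` draws
#' a rounded normal truncated below at `min`; `length_bimodal(l1, l2, w)`
#' draws `l1` with probability `w`, else `l2` (two well-separated modes,
#' as seen for helix lengths that differ between taxonomic groups).
#'
#' @param l,l1,l2 lengths (positive integers).
#' @param mean,sd normal parameters.
#' @param min truncation floor (default 1).
#' @param w weight of the first mode.
#' @return A `length_dist` list with a `draw(n)` function and
#'   `min_length`.
#' @name length_dists
NULL

#' @rdname length_dists
#' @export
length_constant <- function(l) {
  stopifnot(l >= 1)
  structure(list(type = "constant", min_length = as.integer(l),
                 draw = function(n) rep(as.integer(l), n)),
            class = "length_dist")
}

#' @rdname length_dists
#' @export
length_dnorm <- function(mean, sd, min = 1L) {
  stopifnot(mean >= min, sd >= 0)
  structure(list(type = "dnorm", min_length = as.integer(min),
                 draw = function(n) pmax(as.integer(min),
                                         as.integer(round(stats::rnorm(n, mean, sd))))),
            class = "length_dist")
}

#' @rdname length_dists
#' @export
length_bimodal <- function(l1, l2, w = 0.5) {
  stopifnot(l1 >= 1, l2 >= 1, w >= 0, w <= 1)
  structure(list(type = "bimodal", min_length = as.integer(min(l1, l2)),
                 draw = function(n) sample(as.integer(c(l1, l2)), n,
                                           replace = TRUE,
                                           prob = c(w, 1 - w))),
            class = "length_dist")
}

#' Specify a synthetic protein family
#'
#' @param n_domains number of domains to generate.
#' @param classes list of [class_spec()]s.
#' @param background amino-acid emission probabilities (named over the
#'   20 standard codes); default uniform, which makes information-content
#'   baselines analytic.
#' @param group_label optional superkingdom assigned to every domain.
#' @param seed master seed; all (domain, class) substreams derive from
#'   it.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_domains, classes, background = NULL,
                        group_label = NULL, seed = 1L) {
  stopifnot(n_domains >= 1, length(classes) > 0,
            all(vapply(classes, inherits, logical(1), "class_spec")))
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), AMINO_ACIDS)
  stopifnot(identical(sort(names(background)), sort(AMINO_ACIDS)),
            all(background >= 0), abs(sum(background) - 1) < 1e-9)
  labels <- vapply(classes, `[[`, character(1), "label")
  stopifnot(!anyDuplicated(labels))
  structure(list(n_domains = as.integer(n_domains),
                 classes = stats::setNames(classes, labels),
                 background = background[AMINO_ACIDS],
                 group_label = group_label,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# Deterministic substream seed from (master, domain counter, class
# label): a 31-bit multiplicative string hash, so streams are stable
# when classes are added or reordered.
substream_seed <- function(master, domain_idx, label) {
  h <- (as.numeric(master) %% 2147483647) + 1
  for (code in c(domain_idx, utf8ToInt(label))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_preserved_rng <- function(expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  }
  expr
}

#' Generate a synthetic annotation set
#'
#' For each domain and class: presence is Bernoulli(`occurrence_prob`);
#' length is drawn from the class's length distribution; the sequence is
#' drawn i.i.d. from the background except at the planted consensus
#' position, which emits the consensus amino acid with its stated
#' probability (otherwise a background draw). Residue numbers are laid
#' out consecutively with a 5-residue gap between classes. Byte-identical
#' for a fixed spec (including seed); the caller's RNG state is left
#' untouched.
#'
#' @param spec a [family_spec()].
#' @return An [annotation_set()] whose `class_order` follows the spec.
#' @export
generate_annotation_set <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_preserved_rng({
    domains <- lapply(seq_len(spec$n_domains), function(d) {
      sses <- list()
      start <- 1L
      for (cls in spec$classes) {
        set.seed(substream_seed(spec$seed, d, cls$label))
        present <- stats::runif(1) < cls$occurrence_prob
        len <- cls$length_dist$draw(1L)
        seq_chars <- sample(AMINO_ACIDS, len, replace = TRUE,
                            prob = spec$background)
        if (!is.null(cls$consensus) &&
            stats::runif(1) < cls$consensus$prob)
          seq_chars[cls$consensus$position] <- cls$consensus$aa
        if (present) {
          sses[[cls$label]] <- sse_annotation(
            cls$label, cls$sse_type, start, start + len - 1L,
            sequence = paste(seq_chars, collapse = ""))
        }
        start <- start + len + 5L
      }
      domain_record(sprintf("syn%04d", d), unname(sses),
                    superkingdom = spec$group_label)
    })
    annotation_set(domains,
                   class_order = names(spec$classes))
  })
}

#' Generate two synthetic groups from a master seed
#'
#' Independent generation of two annotation sets (e.g. a bacterial-like
#' and a eukaryotic-like group) with distinct substreams derived from
#' one master seed.
#'
#' @param specA,specB [family_spec()]s; their own `seed` fields are
#'   replaced by seeds derived from `master_seed`.
#' @param master_seed integer.
#' @return List of two [annotation_set()]s named `A` and `B`.
#' @export
generate_two_groups <- function(specA, specB, master_seed = 1L) {
  specA$seed <- substream_seed(master_seed, 1L, "groupA")
  specB$seed <- substream_seed(master_seed, 2L, "groupB")
  list(A = generate_annotation_set(specA),
       B = generate_annotation_set(specB))
}

#' A P450-like default family specification
#'
#' Study conditions shaped on the anatomy of the cytochrome P450 fold:
#' a near-ubiquitous long core helix (I-like, 33 residues, planted
#' conserved position), a fully conserved mid-size helix (C-like, with a
#' strong consensus residue at position 8 mirroring the reference
#' residue of helix C), a bimodal helix (J-like, 10 vs 15 residues), a
#' short often-missing helix (B''-like, 3-4 residues, 61% occurrence),
#' and a short strand pair. Occurrence probabilities and lengths follow
#' the family-wide figures reported for the fold.
#'
#' @param n_domains number of domains (default 50).
#' @param seed master seed.
#' @return A [family_spec()].
#' @export
cyp_like_family_spec <- function(n_domains = 50, seed = 1L) {
  family_spec(
    n_domains = n_domains,
    classes = list(
      class_spec("I", occurrence_prob = 0.99,
                 length_dist = length_dnorm(33, 1.5, min = 25),
                 consensus = list(position = 12, aa = "G", prob = 0.95)),
      class_spec("C", occurrence_prob = 0.99,
                 length_dist = length_dnorm(15, 1, min = 10),
                 consensus = list(position = 8, aa = "R", prob = 0.9)),
      class_spec("J", occurrence_prob = 0.97,
                 length_dist = length_bimodal(10, 15, w = 2 / 3),
                 consensus = list(position = 4, aa = "E", prob = 0.85)),
      class_spec("B''", occurrence_prob = 0.61,
                 length_dist = length_dnorm(3.5, 0.5, min = 3)),
      class_spec("b1-1", occurrence_prob = 1,
                 length_dist = length_dnorm(5, 1, min = 3),
                 consensus = list(position = 2, aa = "W", prob = 0.9),
                 sse_type = "strand"),
      class_spec("b5-1", occurrence_prob = 0.25,
                 length_dist = length_constant(2),
                 sse_type = "strand")),
    seed = seed)
}
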