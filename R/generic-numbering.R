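# Generic residue numbering anchored at @X.50.
#
# Once the per-class alignment and its reference column are fixed, every
# aligned residue gets a family-level identifier @<label>.<NN>: the
# residue in the reference column is @X.50 and neighbours follow by
# column arithmetic (no internal gaps, so numbers within one domain's SSE
# are consecutive). Example: in helix C of structure 2nnj (residues
# 117-131, reference residue R124), W120 is @C.46.

#' Assign generic residue numbers to every aligned domain
#'
#' A residue in alignment column `j` receives generic number
#' `50 + (j - reference_column)`. Residue numbers run consecutively from
#' each domain's SSE start. Domains whose block does not span the
#' reference column still get numbers by the same arithmetic and are
#' flagged in `extrapolated`.
#'
#' @param alignment an `endgap_alignment` whose sequence ids are domain
#'   ids.
#' @param reference_column alignment column of the reference residue.
#' @param label SSE class label (the `X` of `@X.50`).
#' @param residue_starts named integer vector or list: start residue
#'   number of the aligned segment in each domain; must cover every
#'   sequence id in the alignment.
#' @return An object of class `generic_numbering` with `sse_label`,
#'   `reference_column`, `per_domain` (one data.frame of
#'   `residue_number`, `generic_number` per domain) and `extrapolated`
#'   (ids of domains not spanning the reference column).
#' @export
assign_generic_numbers <- function(alignment, reference_column, label,
                                   residue_starts) {
  stopifnot(inherits(alignment, "endgap_alignment"))
  reference_column <- as.integer(reference_column)
  stopifnot(reference_column >= 1L, reference_column <= alignment$width)
  residue_starts <- unlist(residue_starts)
  missing <- setdiff(alignment$sequence_ids, names(residue_starts))
  if (length(missing))
    stop(sprintf("residue_starts missing for domains: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  per_domain <- list()
  extrapolated <- character(0)
  for (k in seq_along(alignment$sequence_ids)) {
    id <- alignment$sequence_ids[k]
    len <- nchar(alignment$sequences[k])
    cols <- alignment$offsets[k] + seq_len(len)   # occupied columns
    generic <- 50L + (cols - reference_column)
    if (any(generic < 1L))
      stop(sprintf(
        "domain '%s': generic number below 1 (SSE extends more than 49 residues before the reference)",
        id), call. = FALSE)
    if (!(reference_column %in% cols))
      extrapolated <- c(extrapolated, id)
    per_domain[[id]] <- data.frame(
      residue_number = as.integer(residue_starts[[id]]) + seq_len(len) - 1L,
      generic_number = generic)
  }
  structure(list(sse_label = label, reference_column = reference_column,
                 per_domain = per_domain, extrapolated = extrapolated),
            class = "generic_numbering")
}

#' @export
print.generic_numbering <- function(x, ...) {
  cat(sprintf("generic_numbering '@%s': reference column %d, %d domains%s\n",
              x$sse_label, x$reference_column, length(x$per_domain),
              if (length(x$extrapolated))
                sprintf(" (%d extrapolated)", length(x$extrapolated)) else ""))
  invisible(x)
}

#' Flatten a generic numbering into a table
#'
#' @param numbering a `generic_numbering` (or a list of them).
#' @return data.frame with columns `domain_id`, `residue_number`, `label`,
#'   `generic_number`.
#' @export
numbering_table <- function(numbering) {
  if (inherits(numbering, "generic_numbering")) numbering <- list(numbering)
  do.call(rbind, unlist(lapply(numbering, function(gn) {
    lapply(names(gn$per_domain), function(id) {
      df <- gn$per_domain[[id]]
      data.frame(domain_id = id, residue_number = df$residue_number,
                 label = gn$sse_label, generic_number = df$generic_number)
    })
  }), recursive = FALSE))
}

#' Format a residue identifier with its generic number
#'
#' Produces the line notation `W120^@C.46` (residue + generic number),
#' `W120A^@C.46` (with a mutation) or the generic-only form `@C.46`.
#'
#' @param aa one-letter amino-acid code; `NULL` together with
#'   `residue_number = NULL` gives the generic-only form.
#' @param residue_number residue number in the structure, or `NULL`.
#' @param label SSE class label.
#' @param generic_number integer generic number.
#' @param mutant_aa optional one-letter code of a substituted residue.
#' @return A string.
#' @export
format_residue <- function(aa = NULL, residue_number = NULL, label,
                           generic_number, mutant_aa = NULL) {
  check_aa <- function(x, what) {
    if (!is.character(x) || nchar(x) != 1L ||
        !toupper(x) %in% c(AMINO_ACIDS, "X"))
      stop(sprintf("invalid one-letter %s code: '%s'", what, x),
           call. = FALSE)
    toupper(x)
  }
  generic <- sprintf("@%s.%d", label, as.integer(generic_number))
  if (is.null(residue_number)) return(generic)
  aa <- check_aa(aa, "amino-acid")
  mut <- if (is.null(mutant_aa)) "" else check_aa(mutant_aa, "mutant")
  sprintf("%s%d%s^%s", aa, as.integer(residue_number), mut, generic)
}
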