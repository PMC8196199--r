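# Offline dataset curation: non-redundant selection (one best-quality
# domain per UniProt accession), superkingdom split, and template
# selection from a precomputed pairwise structure-similarity (Q-score)
# matrix. Network retrieval is deliberately out of scope: the module
# consumes exported tables.

#' Select a non-redundant domain table
#'
#' Keeps exactly one domain per distinct UniProt accession -- the one
#' with the highest quality score (ties broken by lexicographically
#' smallest `domain_id`). Domains without a UniProt mapping are dropped
#' with a message.
#'
#' @param meta data.frame with columns `domain_id`, `uniprot_id`,
#'   `quality` (and any others, preserved).
#' @return The filtered data.frame, in order of first appearance of each
#'   UniProt accession.
#' @export
select_nonredundant <- function(meta) {
  stopifnot(is.data.frame(meta),
            all(c("domain_id", "uniprot_id", "quality") %in% names(meta)))
  mapped <- !is.na(meta$uniprot_id) & nzchar(meta$uniprot_id)
  if (any(!mapped))
    message(sprintf("dropping %d domain(s) with no UniProt mapping: %s",
                    sum(!mapped),
                    paste(meta$domain_id[!mapped], collapse = ", ")))
  meta <- meta[mapped, , drop = FALSE]
  if (nrow(meta) == 0L) {
    warning("no UniProt-mapped domains: empty non-redundant set")
    return(meta)
  }
  keep <- unlist(lapply(split(seq_len(nrow(meta)),
                              factor(meta$uniprot_id,
                                     levels = unique(meta$uniprot_id))),
                        function(idx) {
    q <- meta$quality[idx]
    q[is.na(q)] <- -Inf
    best <- idx[q == max(q)]
    best[order(meta$domain_id[best])][1L]
  }))
  out <- meta[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split an annotation set by superkingdom
#'
#' Partitions the domains into Bacteria / Eukaryota / Archaea / Viruses
#' subsets using either the domains' own metadata or a metadata table;
#' domains with no superkingdom go to an `"unknown"` bucket.
#'
#' @param set an [annotation_set()].
#' @param meta optional data.frame with `domain_id` and `superkingdom`
#'   columns overriding the records' own metadata.
#' @return Named list of [annotation_set()]s (only nonempty buckets),
#'   each preserving the original `class_order`.
#' @export
split_by_superkingdom <- function(set, meta = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  kingdom <- vapply(set$domains, function(d) {
    sk <- d$superkingdom
    if (!is.null(meta)) {
      i <- match(d$domain_id, meta$domain_id)
      if (!is.na(i) && nzna(meta$superkingdom[i])) sk <- meta$superkingdom[i]
    }
    if (is.null(sk) || is.na(sk)) "unknown" else sk
  }, character(1))
  lapply(split(unname(set$domains), kingdom), annotation_set,
         class_order = set$class_order)
}

#' Read a pairwise similarity (Q-score) matrix from TSV
#'
#' Square matrix with ids as both header and first column; validated to
#' be symmetric (tolerance 1e-9) with unit diagonal.
#'
#' @param path TSV file path.
#' @return Numeric matrix with id dimnames.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  validate_similarity_matrix(m)
  m
}

validate_similarity_matrix <- function(m) {
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("similarity matrix needs matching row/column ids", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-9)
    stop("similarity matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-9))
    stop("similarity matrix diagonal must be 1", call. = FALSE)
  if (any(m < 0 | m > 1))
    stop("similarity scores must lie in [0, 1]", call. = FALSE)
  invisible(m)
}

#' Select the template structure from a similarity matrix
#'
#' For each structure, `q_avg` is the mean pairwise similarity against
#' all the other structures; the template is the structure with the
#' highest `q_avg` (the "most average" structure), ties broken by id
#' order.
#'
#' @param matrix square symmetric similarity matrix (ids as dimnames),
#'   e.g. from [read_similarity_matrix()].
#' @return List with `template` (id) and `q_avg` (named numeric vector).
#' @export
select_template <- function(matrix) {
  validate_similarity_matrix(matrix)
  n <- nrow(matrix)
  if (n < 2L) stop("need at least 2 structures", call. = FALSE)
  q_avg <- (rowSums(matrix) - diag(matrix)) / (n - 1)
  list(template = rownames(matrix)[which.max(q_avg)], q_avg = q_avg)
}
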