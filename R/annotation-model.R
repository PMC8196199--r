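# Domain types and I/O for per-domain SSE annotations.
#
# An "SSE" is a contiguous helix or beta-strand segment; an "SSE class" is
# the set of equivalent SSEs across homologous structures that share one
# label (e.g. helix C, strand beta1-4). Annotations arrive as one JSON file
# per protein domain plus an optional domain metadata table.

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a single SSE annotation
#'
#' One labelled secondary structure element of one protein domain. Residue
#' ranges are 1-based and inclusive at both ends, so an SSE spanning
#' residues 284--316 has 33 residues.
#'
#' @param label SSE class label, e.g. `"C"`, `"I"`, `"b1-1"`.
#' @param sse_type `"helix"` or `"strand"` (JSON files use `"H"`/`"E"`).
#' @param start,end first and last residue number (inclusive).
#' @param sequence optional one-letter amino-acid string; may contain `"X"`
#'   for non-standard residues. When given, its length must equal
#'   `end - start + 1`.
#' @param metric optional non-negative annotation confidence metric.
#' @param sheet_id optional beta-sheet connectivity group id.
#' @return An object of class `sse_annotation`.
#' @export
sse_annotation <- function(label, sse_type, start, end, sequence = NULL,
                           metric = NULL, sheet_id = NULL) {
  sse_type <- match.arg(sse_type, c("helix", "strand"))
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("SSE label must be a nonempty string", call. = FALSE)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end)
    stop(sprintf("SSE '%s': invalid residue range %s-%s (need start <= end)",
                 label, start, end), call. = FALSE)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != end - start + 1L)
      stop(sprintf(
        "SSE '%s': sequence length %d does not match residue range %d-%d (%d residues)",
        label, nchar(sequence), start, end, end - start + 1L), call. = FALSE)
    bad <- setdiff(strsplit(sequence, "")[[1]], c(AMINO_ACIDS, "X"))
    if (length(bad))
      stop(sprintf("SSE '%s': invalid residue letters: %s",
                   label, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(metric)) {
    metric <- as.numeric(metric)
    if (is.na(metric) || metric < 0)
      stop(sprintf("SSE '%s': metric must be non-negative", label),
           call. = FALSE)
  }
  structure(list(label = label, sse_type = sse_type, start = start,
                 end = end, sequence = sequence, metric = metric,
                 sheet_id = sheet_id),
            class = "sse_annotation")
}

#' Length of an SSE in residues
#'
#' Inclusive residue count `end - start + 1`; e.g. helix I spanning
#' 284--316 has length 33.
#'
#' @param sse An [sse_annotation()].
#' @return Positive integer length.
#' @export
sse_length <- function(sse) {
  stopifnot(inherits(sse, "sse_annotation"))
  sse$end - sse$start + 1L
}

#' Construct a domain record
#'
#' One protein domain (typically a PDB chain) together with its SSE
#' annotations and optional metadata.
#'
#' @param domain_id nonempty id, conventionally PDB id + chain (`"2nnjA"`).
#' @param sses list of [sse_annotation()] objects; labels must be unique.
#' @param uniprot_id,superkingdom,quality optional metadata: UniProt
#'   accession, one of Bacteria/Eukaryota/Archaea/Viruses, and a numeric
#'   structure quality score.
#' @return An object of class `domain_record`.
#' @export
domain_record <- function(domain_id, sses = list(), uniprot_id = NULL,
                          superkingdom = NULL, quality = NULL) {
  if (!is.character(domain_id) || length(domain_id) != 1L || !nzchar(domain_id))
    stop("domain_id must be a nonempty string", call. = FALSE)
  stopifnot(all(vapply(sses, inherits, logical(1), "sse_annotation")))
  labels <- vapply(sses, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop(sprintf("domain '%s': duplicated SSE labels: %s", domain_id,
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")),
         call. = FALSE)
  if (!is.null(superkingdom))
    superkingdom <- match.arg(superkingdom,
                              c("Bacteria", "Eukaryota", "Archaea", "Viruses"))
  structure(list(domain_id = domain_id, sses = stats::setNames(sses, labels),
                 uniprot_id = uniprot_id, superkingdom = superkingdom,
                 quality = if (is.null(quality)) NULL else as.numeric(quality)),
            class = "domain_record")
}

#' Construct an annotation set
#'
#' A collection of domain records plus the canonical ordering of SSE class
#' labels. Labels that occur in domains but not in `class_order` are kept
#' and reported as unclassified, never dropped.
#'
#' @param domains list of [domain_record()] objects with unique ids.
#' @param class_order character vector of canonical SSE labels; defaults to
#'   the labels in order of first appearance across domains.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(domains = list(), class_order = NULL) {
  stopifnot(all(vapply(domains, inherits, logical(1), "domain_record")))
  ids <- vapply(domains, `[[`, character(1), "domain_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicated domain ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  seen <- unique(unlist(lapply(domains, function(d) names(d$sses))))
  if (is.null(seen)) seen <- character(0)
  if (is.null(class_order)) class_order <- seen
  unclassified <- setdiff(seen, class_order)
  structure(list(domains = stats::setNames(domains, ids),
                 class_order = class_order,
                 unclassified = unclassified),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d domains, %d SSE classes",
              length(x$domains), length(x$class_order)))
  if (length(x$unclassified))
    cat(sprintf(" (+%d unclassified: %s)", length(x$unclassified),
                paste(x$unclassified, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$domains)

parse_annotation_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("malformed JSON in '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  # best-effort mapping of SecStrAPI-style exports: SSEs may live under
  # doc$sses or doc$annotations[[domain]]$secondary_structure_elements
  domain_id <- doc$domain %||% doc$domain_id %||%
    tools::file_path_sans_ext(basename(path))
  sses_raw <- doc$sses %||% doc$secondary_structure_elements
  if (is.null(sses_raw))
    stop(sprintf("'%s': no 'sses' field found", path), call. = FALSE)
  sses <- lapply(sses_raw, function(s) {
    typ <- s$type %||% s$sse_type
    typ <- switch(toupper(substr(typ, 1, 1)),
                  H = "helix", G = "helix", E = "strand",
                  stop(sprintf("'%s': SSE '%s': unknown type '%s'",
                               path, s$label, typ), call. = FALSE))
    tryCatch(
      sse_annotation(label = s$label, sse_type = typ,
                     start = s$start, end = s$end,
                     sequence = s$sequence, metric = s$metric,
                     sheet_id = s$sheet_id),
      error = function(e) stop(sprintf("'%s': %s", path, conditionMessage(e)),
                               call. = FALSE))
  })
  domain_record(domain_id, sses)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an annotation set from per-domain JSON files
#'
#' Each file holds one domain: `{"domain": id, "sses": [{"label", "type"
#' ("H"/"E"), "start", "end", "sequence", "metric"?, "sheet_id"?}, ...]}`.
#' An optional metadata table (see [read_domain_metadata()]) joins
#' `uniprot_id`, `superkingdom` and `quality` columns by `domain_id`.
#'
#' @param paths character vector of JSON file paths.
#' @param metadata optional data.frame with at least a `domain_id` column.
#' @param class_order optional canonical label order.
#' @return An [annotation_set()].
#' @export
load_annotation_set <- function(paths, metadata = NULL, class_order = NULL) {
  domains <- lapply(paths, parse_annotation_json)
  if (!is.null(metadata)) {
    stopifnot("domain_id" %in% names(metadata))
    idx <- match(vapply(domains, `[[`, character(1), "domain_id"),
                 metadata$domain_id)
    domains <- Map(function(d, i) {
      if (is.na(i)) return(d)
      row <- metadata[i, ]
      domain_record(d$domain_id, unname(d$sses),
                    uniprot_id = if (nzna(row$uniprot_id)) row$uniprot_id,
                    superkingdom = if (nzna(row$superkingdom)) row$superkingdom,
                    quality = if (nzna(row$quality)) row$quality)
    }, domains, idx)
  }
  annotation_set(domains, class_order = class_order)
}

nzna <- function(x) {
  !is.null(x) && length(x) == 1L && !is.na(x) &&
    (!is.character(x) || nzchar(x))
}

#' Write an annotation set back to per-domain JSON files
#'
#' Inverse of [load_annotation_set()]; optional generic-number arrays from
#' [assign_generic_numbers()] are embedded per SSE.
#'
#' @param set an [annotation_set()].
#' @param dir output directory (created if missing).
#' @param numbering optional list of `generic_numbering` objects to embed.
#' @return Invisibly, the written file paths.
#' @export
write_annotation_set <- function(set, dir, numbering = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num_by_dom <- list()
  for (gn in numbering) {
    for (dom in names(gn$per_domain))
      num_by_dom[[dom]][[gn$sse_label]] <- gn$per_domain[[dom]]
  }
  paths <- vapply(set$domains, function(d) {
    sses <- lapply(unname(d$sses), function(s) {
      out <- list(label = s$label,
                  type = if (s$sse_type == "helix") "H" else "E",
                  start = s$start, end = s$end)
      if (!is.null(s$sequence)) out$sequence <- s$sequence
      if (!is.null(s$metric)) out$metric <- s$metric
      if (!is.null(s$sheet_id)) out$sheet_id <- s$sheet_id
      gnum <- num_by_dom[[d$domain_id]][[s$label]]
      if (!is.null(gnum)) out$generic_numbers <- gnum$generic_number
      out
    })
    path <- file.path(dir, paste0(d$domain_id, ".sses.json"))
    jsonlite::write_json(list(domain = d$domain_id, sses = sses), path,
                         auto_unbox = TRUE, digits = NA)
    path
  }, character(1))
  invisible(unname(paths))
}

#' Read a domain metadata table
#'
#' TSV with columns `domain_id`, `pdb`, `chain`, `uniprot_id`,
#' `superkingdom`, `quality` (missing values empty or NA).
#'
#' @param path TSV file path.
#' @return A data.frame.
#' @export
read_domain_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  stopifnot("domain_id" %in% names(df))
  df
}

#' Extract per-domain sequences of one SSE class
#'
#' One entry per domain in which the SSE exists (>= 1 annotated residue);
#' domains lacking the class are omitted. Order follows the set's domains.
#'
#' @param set an [annotation_set()].
#' @param label SSE class label; must be in `class_order` or among the
#'   unclassified labels.
#' @return Named character vector of sequences (names are domain ids).
#' @export
class_sequences <- function(set, label) {
  stopifnot(inherits(set, "annotation_set"))
  if (!label %in% c(set$class_order, set$unclassified))
    stop(sprintf("unknown SSE class label '%s'", label), call. = FALSE)
  out <- lapply(set$domains, function(d) {
    s <- d$sses[[label]]
    if (is.null(s) || is.null(s$sequence)) NULL else s$sequence
  })
  unlist(out[!vapply(out, is.null, logical(1))]) %||%
    stats::setNames(character(0), character(0))
}

#' Write sequences of one SSE class as FASTA
#'
#' Headers are domain ids; lines wrap at 60 columns.
#'
#' @param sequences named character vector (names = domain ids).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_class_fasta <- function(sequences, path) {
  if (length(sequences) == 0L) {
    warning("writing empty FASTA file: no sequences for this class")
    file.create(path)
    return(invisible(path))
  }
  if (any(!nzchar(sequences)))
    stop("empty sequence cannot be written to FASTA", call. = FALSE)
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a class FASTA written by [write_class_fasta()]
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_class_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}
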