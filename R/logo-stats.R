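# Per-column sequence-logo statistics on an end-gap alignment.
#
# For column i: p_i^a is the fraction of ALL sequences carrying amino acid
# a at i; p_i (occupancy) is the fraction carrying any residue (gap
# excluded; 'X' counts as occupied but as none of the 20 amino acids).
# Information content, in bits:
#
#   R_i = log2(20) + sum_{a in A} (p_i^a / p_i) * log2(p_i^a / p_i)
#
# with A the 20 standard amino acids and 0*log2(0) := 0, so R_i ranges
# from 0 (20 equiprobable residues) to log2(20) ~ 4.32 (one perfectly
# conserved residue). Conservation c_i = p_i * R_i is the area of the
# logo column (width p_i, height R_i).

#' Build per-column logo statistics from an alignment
#'
#' @param alignment an `endgap_alignment` (no internal gaps, no all-gap
#'   columns).
#' @param label SSE class label carried into the result.
#' @return An object of class `sse_logo` with elements `sse_label`,
#'   `columns` (data.frame: `index`, `occupancy`, `information`,
#'   `conservation`, plus one fraction column per amino acid),
#'   `fractions` (20 x width matrix of p_i^a), `n_sequences`, `r_avg`,
#'   `reference_index`, `eligible`.
#' @export
build_logo <- function(alignment, label = "") {
  stopifnot(inherits(alignment, "endgap_alignment"))
  n <- length(alignment$sequences)
  if (n == 0L) stop("empty alignment", call. = FALSE)
  w <- alignment$width
  chars <- matrix("-", nrow = n, ncol = w)
  for (k in seq_len(n)) {
    s <- strsplit(alignment$sequences[k], "")[[1]]
    chars[k, alignment$offsets[k] + seq_along(s)] <- s
  }
  counts <- vapply(AMINO_ACIDS,
                   function(a) colSums(chars == a), numeric(w))
  if (w == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, AMINO_ACIDS))
  fractions <- t(counts) / n                       # 20 x w, p_i^a
  occupancy <- colSums(chars != "-") / n           # includes 'X'
  information <- vapply(seq_len(w), function(i) {
    q <- fractions[, i] / occupancy[i]
    q <- q[q > 0]
    log2(20) + sum(q * log2(q))
  }, numeric(1))
  conservation <- occupancy * information
  cols <- data.frame(index = seq_len(w), occupancy = occupancy,
                     information = information, conservation = conservation)
  cols <- cbind(cols, as.data.frame(t(fractions)))
  ref <- which.max(conservation)  # leftmost maximum
  logo <- structure(list(
    sse_label = label, columns = cols, fractions = fractions,
    n_sequences = n,
    r_avg = sum(occupancy * information) / sum(occupancy),
    reference_index = ref,
    eligible = conservation[ref] > 2), class = "sse_logo")
  logo
}

#' @export
print.sse_logo <- function(x, ...) {
  cat(sprintf(
    "sse_logo '%s': %d columns, %d sequences, R_avg = %.2f bits, reference column %d (c = %.2f bits%s)\n",
    x$sse_label, nrow(x$columns), x$n_sequences, x$r_avg,
    x$reference_index, x$columns$conservation[x$reference_index],
    if (x$eligible) ", eligible" else ", not eligible"))
  invisible(x)
}

#' Occupancy-weighted average information content of a logo
#'
#' `R_avg = sum(p_i * R_i) / sum(p_i)` -- the average column height, used
#' to rank SSE classes from most conserved to most variable.
#'
#' @param logo an `sse_logo`.
#' @return Numeric, in bits, within `[0, log2(20)]`.
#' @export
average_information <- function(logo) {
  stopifnot(inherits(logo, "sse_logo"))
  p <- logo$columns$occupancy
  if (all(p == 0)) stop("all columns empty: R_avg undefined", call. = FALSE)
  sum(p * logo$columns$information) / sum(p)
}

#' Select the reference column of a logo
#'
#' The reference residue anchors generic numbering: the column with the
#' greatest conservation `c_i` (leftmost on ties). The class is eligible
#' for generic numbering only when `max(c_i)` strictly exceeds 2 bits.
#'
#' @param logo an `sse_logo`.
#' @return List with `index` (column) and `eligible` (logical).
#' @export
select_reference <- function(logo) {
  stopifnot(inherits(logo, "sse_logo"))
  if (nrow(logo$columns) == 0L) stop("empty logo", call. = FALSE)
  ci <- logo$columns$conservation
  idx <- which.max(ci)
  list(index = idx, eligible = ci[idx] > 2)
}

#' Write logo statistics as TSV
#'
#' One row per column: index, occupancy, information, conservation, and
#' the 20 per-amino-acid fractions.
#'
#' @param logo an `sse_logo`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_logo_tsv <- function(logo, path) {
  utils::write.table(logo$columns, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Render a sequence logo figure
#'
#' Classic stacked-letter logo: column width proportional to occupancy
#' `p_i`, total letter height `R_i`, letters stacked by increasing
#' frequency. Requires ggplot2.
#'
#' @param logo an `sse_logo`.
#' @param generic_offsets optional integer vector of generic numbers used
#'   as x labels (e.g. `46:60`); defaults to column indices.
#' @return A ggplot object.
#' @export
plot_logo <- function(logo, generic_offsets = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_logo requires the ggplot2 package", call. = FALSE)
  stopifnot(inherits(logo, "sse_logo"))
  w <- nrow(logo$columns)
  rects <- do.call(rbind, lapply(seq_len(w), function(i) {
    p <- logo$fractions[, i]
    p <- p[p > 0]
    if (!length(p)) return(NULL)
    rel <- p / logo$columns$occupancy[i]
    h <- rel * logo$columns$information[i]
    ord <- order(h)
    y1 <- cumsum(h[ord])
    data.frame(column = i, aa = names(p)[ord],
               xmin = i - 0.45 * logo$columns$occupancy[i],
               xmax = i + 0.45 * logo$columns$occupancy[i],
               ymin = c(0, y1[-length(y1)]), ymax = y1)
  }))
  labs <- if (is.null(generic_offsets)) seq_len(w) else generic_offsets
  ggplot2::ggplot(rects) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$aa),
                       colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(x = .data$column,
                                    y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$aa),
                       size = 2.5) +
    ggplot2::scale_x_continuous(breaks = seq_len(w), labels = labs) +
    ggplot2::labs(x = "position", y = "information (bits)",
                  title = logo$sse_label) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
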