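# Family anatomy statistics: per-class occurrence frequencies with
# Agresti-Coull confidence intervals, length-distribution summaries, and
# the anatomy report ranking SSE classes by average information content.

#' Agresti-Coull confidence interval for a binomial proportion
#'
#' With `z` the standard normal `1 - alpha/2` quantile, the adjusted
#' counts are `n~ = n + z^2`, `p~ = (k + z^2/2) / n~`, and the interval is
#' `p~ +/- z * sqrt(p~ (1 - p~) / n~)`, clamped to `[0, 1]`.
#'
#' @param k number of successes.
#' @param n number of trials (`n >= 1`).
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @return Named numeric vector `c(low, high)`.
#' @export
agresti_coull <- function(k, n, alpha = 0.05) {
  stopifnot(n >= 1, k >= 0, k <= n)
  z <- stats::qnorm(1 - alpha / 2)
  n_adj <- n + z^2
  p_adj <- (k + z^2 / 2) / n_adj
  half <- z * sqrt(p_adj * (1 - p_adj) / n_adj)
  c(low = max(0, p_adj - half), high = min(1, p_adj + half))
}

class_presence <- function(set, label) {
  vapply(set$domains, function(d) !is.null(d$sses[[label]]), logical(1))
}

all_labels <- function(set) c(set$class_order, set$unclassified)

#' Occurrence frequency of every SSE class
#'
#' An SSE class "occurs" in a domain when it is annotated there with at
#' least one residue; the frequency is the fraction of domains containing
#' it, with an Agresti-Coull confidence interval.
#'
#' @param set an [annotation_set()] with at least one domain.
#' @param alpha significance level for the intervals.
#' @return data.frame with columns `label`, `count`, `total`, `frequency`,
#'   `ci_low`, `ci_high`, `alpha`.
#' @export
occurrence_stats <- function(set, alpha = 0.05) {
  stopifnot(inherits(set, "annotation_set"))
  n <- length(set$domains)
  if (n == 0L) stop("empty annotation set", call. = FALSE)
  labels <- all_labels(set)
  rows <- lapply(labels, function(lab) {
    k <- sum(class_presence(set, lab))
    ci <- agresti_coull(k, n, alpha)
    data.frame(label = lab, count = k, total = n, frequency = k / n,
               ci_low = ci[["low"]], ci_high = ci[["high"]], alpha = alpha)
  })
  do.call(rbind, rows)
}

class_lengths <- function(set, label) {
  out <- lapply(set$domains, function(d) {
    s <- d$sses[[label]]
    if (is.null(s)) NULL else sse_length(s)
  })
  as.integer(unlist(out))
}

#' Length distribution summary of every SSE class
#'
#' Lengths are inclusive residue counts over the domains where the class
#' exists; absent SSEs contribute nothing to the distribution. The median
#' of an even-sized multiset is the mean of the two central values.
#'
#' @param set an [annotation_set()].
#' @return Named list of `length_summary` objects (`label`, `lengths`,
#'   `mean`, `median`, `n_present`).
#' @export
length_stats <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  labels <- all_labels(set)
  out <- lapply(labels, function(lab) {
    lens <- class_lengths(set, lab)
    structure(list(label = lab, lengths = lens,
                   mean = if (length(lens)) mean(lens) else NA_real_,
                   median = if (length(lens)) stats::median(lens) else NA_real_,
                   n_present = length(lens)),
              class = "length_summary")
  })
  stats::setNames(out, labels)
}

#' @export
print.length_summary <- function(x, ...) {
  cat(sprintf("length_summary '%s': n = %d, mean = %.2f, median = %s\n",
              x$label, x$n_present, x$mean, format(x$median)))
  invisible(x)
}

#' Family anatomy report
#'
#' One row per SSE class with its representative residue range (taken
#' from `reference_domain` when it contains the SSE), average information
#' content, occurrence frequency and mean length, sorted from the most
#' conserved class (highest `r_avg`) to the most variable; ties keep the
#' canonical label order.
#'
#' @param set an [annotation_set()].
#' @param logos named list of `sse_logo` objects (one per class); classes
#'   without a logo get `NA` `r_avg` with a warning.
#' @param reference_domain optional domain id whose residue ranges label
#'   the rows.
#' @return data.frame with columns `label`, `range`, `r_avg`,
#'   `occurrence`, `mean_length`, `n_present`.
#' @export
anatomy_report <- function(set, logos, reference_domain = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  occ <- occurrence_stats(set)
  lens <- length_stats(set)
  labels <- all_labels(set)
  ref <- if (!is.null(reference_domain)) set$domains[[reference_domain]]
  rows <- lapply(labels, function(lab) {
    logo <- logos[[lab]]
    if (is.null(logo))
      warning(sprintf("no logo for class '%s': R_avg reported as NA", lab))
    rng <- ""
    if (!is.null(ref) && !is.null(ref$sses[[lab]])) {
      s <- ref$sses[[lab]]
      rng <- if (s$start == s$end) as.character(s$start) else
        sprintf("%d-%d", s$start, s$end)
    }
    data.frame(label = lab, range = rng,
               r_avg = if (is.null(logo)) NA_real_ else logo$r_avg,
               occurrence = occ$frequency[occ$label == lab],
               mean_length = lens[[lab]]$mean,
               n_present = lens[[lab]]$n_present)
  })
  report <- do.call(rbind, rows)
  # stable sort: ties by canonical label order (current row order)
  report <- report[order(-report$r_avg, na.last = TRUE), ]
  rownames(report) <- NULL
  report
}
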