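# Statistical comparison of two annotation sets (e.g. bacterial vs
# eukaryotic structures) per SSE class. Occurrence is modelled as a
# binomial and compared by the test of equal proportions
# (stats::prop.test, chi-square with continuity correction by default);
# lengths are compared by the two-sample Kolmogorov-Smirnov test
# (stats::ks.test), applied only where the two medians differ -- equal
# medians yield a skipped result, mirroring the gating used for
# distribution comparisons of integer-valued lengths.

comparison_result <- function(label, kind, statistic = NA_real_,
                              p_value = NA_real_, alpha = 0.05,
                              direction = "none", skipped = FALSE,
                              reason = NA_character_) {
  structure(list(label = label, kind = kind, statistic = statistic,
                 p_value = p_value, alpha = alpha,
                 significant = if (skipped) NA else (p_value < alpha),
                 direction = direction, skipped = skipped, reason = reason),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("compare '%s' (%s): skipped (%s)\n", x$label, x$kind,
                x$reason))
  } else {
    cat(sprintf(
      "compare '%s' (%s): statistic = %.4g, p = %.4g%s, direction = %s\n",
      x$label, x$kind, x$statistic, x$p_value,
      if (x$significant) " *" else "", x$direction))
  }
  invisible(x)
}

#' Compare occurrence of one SSE class between two sets
#'
#' Test of equal proportions on the 2x2 presence table (chi-square, with
#' Yates continuity correction by default).
#'
#' @param setA,setB nonempty [annotation_set()]s.
#' @param label SSE class label.
#' @param alpha significance level.
#' @param correct apply the continuity correction (default `TRUE`).
#' @return A `comparison_result` (`kind = "occurrence"`); `direction`
#'   says which set has the higher sample proportion.
#' @export
compare_occurrence <- function(setA, setB, label, alpha = 0.05,
                               correct = TRUE) {
  nA <- length(setA$domains); nB <- length(setB$domains)
  if (nA == 0L || nB == 0L)
    stop("both annotation sets must be nonempty", call. = FALSE)
  kA <- sum(class_presence(setA, label))
  kB <- sum(class_presence(setB, label))
  direction <- if (kA / nA > kB / nB) "A_higher"
    else if (kA / nA < kB / nB) "B_higher" else "none"
  # both groups at the same boundary (all present or all absent): the
  # 2x2 table has a zero margin and the chi-square is undefined; there
  # is no evidence of a difference
  if (kA + kB == 0L || kA + kB == nA + nB) {
    return(comparison_result(label, "occurrence", statistic = 0,
                             p_value = 1, alpha = alpha,
                             direction = direction))
  }
  ht <- suppressWarnings(
    stats::prop.test(c(kA, kB), c(nA, nB), correct = correct))
  comparison_result(label, "occurrence",
                    statistic = unname(ht$statistic),
                    p_value = ht$p.value, alpha = alpha,
                    direction = direction)
}

#' Compare length distributions of one SSE class between two sets
#'
#' Two-sample Kolmogorov-Smirnov test with the asymptotic two-sided
#' p-value (integer lengths carry ties, so exact small-sample p-values
#' are ill-defined; the asymptotic value is approximate under ties).
#' When the two medians are equal the comparison is skipped; when either
#' set lacks the class entirely it is skipped with reason `"absent"`.
#'
#' @inheritParams compare_occurrence
#' @return A `comparison_result` (`kind = "length"`); `direction` says
#'   which set has the higher median.
#' @export
compare_lengths <- function(setA, setB, label, alpha = 0.05) {
  lenA <- class_lengths(setA, label)
  lenB <- class_lengths(setB, label)
  if (length(lenA) == 0L || length(lenB) == 0L)
    return(comparison_result(label, "length", alpha = alpha,
                             skipped = TRUE, reason = "absent"))
  medA <- stats::median(lenA); medB <- stats::median(lenB)
  # lengths are integers, so medians are multiples of 1/2: comparison of
  # 2*median as integers is exact
  if (round(2 * medA) == round(2 * medB))
    return(comparison_result(label, "length", alpha = alpha,
                             skipped = TRUE, reason = "equal medians"))
  ht <- suppressWarnings(
    stats::ks.test(lenA, lenB, exact = FALSE))
  comparison_result(label, "length",
                    statistic = unname(ht$statistic),
                    p_value = ht$p.value, alpha = alpha,
                    direction = if (medA > medB) "A_higher" else "B_higher")
}

#' Compare two annotation sets across all SSE classes
#'
#' Runs [compare_occurrence()] and [compare_lengths()] for every class
#' in the union of the two sets' canonical orders. No multiple-testing
#' correction is applied by default (each class tested at `alpha`); set
#' `adjust = "BH"` for Benjamini-Hochberg within each test kind.
#'
#' @inheritParams compare_occurrence
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with one row per class and kind: `label`, `kind`,
#'   `statistic`, `p_value`, `p_adjusted`, `significant`, `direction`,
#'   `skipped`, `reason`.
#' @export
compare_sets <- function(setA, setB, alpha = 0.05, correct = TRUE,
                         adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- union(all_labels(setA), all_labels(setB))
  res <- unlist(lapply(labels, function(lab) list(
    compare_occurrence(setA, setB, lab, alpha, correct),
    compare_lengths(setA, setB, lab, alpha))), recursive = FALSE)
  df <- do.call(rbind, lapply(res, function(r)
    data.frame(label = r$label, kind = r$kind, statistic = r$statistic,
               p_value = r$p_value, significant = r$significant,
               direction = r$direction, skipped = r$skipped,
               reason = r$reason)))
  df$p_adjusted <- df$p_value
  if (adjust == "BH") {
    for (k in unique(df$kind)) {
      sel <- df$kind == k & !df$skipped
      df$p_adjusted[sel] <- stats::p.adjust(df$p_value[sel], "BH")
    }
    df$significant <- ifelse(df$skipped, NA, df$p_adjusted < alpha)
  }
  df
}
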