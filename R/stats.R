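# Thin, contract-enforcing wrappers around the standard tests used by
# every enrichment analysis. Margin checks and the "untestable" outcome
# live here so callers never trip an exception on degenerate tables.

#' Pearson chi-square test on a 2x2 overlap table
#'
#' @param a,b element counts overlapping / not overlapping the track.
#' @param c,d the same counts for the reference-element cohort.
#' @param yates apply the Yates continuity correction (default `TRUE`).
#' @return list with `statistic`, `p`, `fold`
#'   (`(a/(a+b)) / (c/(c+d))`) and `testable`; a zero row or column
#'   margin yields `testable = FALSE` with `NA` statistic and p.
#' @export
chi_square_2x2 <- function(a, b, c, d, yates = TRUE) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0))
  margins <- c(a + b, c + d, a + c, b + d)
  fold <- if (a + b > 0 && c + d > 0) (a / (a + b)) / (c / (c + d))
          else NA_real_  # Inf when the reference never overlaps, NaN on 0/0
  if (any(margins == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, fold = fold,
                testable = FALSE))
  }
  ht <- suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                      correct = yates))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       fold = fold, testable = TRUE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving FDR adjustment over one stated test family, capped at
#' 1 and monotone in the input ranking.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (`NA` allowed for
#'   untestable entries; they stay `NA` and do not count toward the
#'   family size).
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact when both samples are small and tie-free, otherwise the normal
#' approximation with tie correction (the behaviour of
#' [stats::wilcox.test()]).
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (the rank-sum U of `x`) and `p`.
#' @export
mann_whitney <- function(x, y) {
  ht <- suppressWarnings(stats::wilcox.test(x, y))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Two-sided p is the sum of hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed the
#' observed table's probability (up to a relative tolerance of 1e-7), the
#' minimum-likelihood convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `p` and the input `table`; an all-zero table gives
#'   `p = 1` with a warning.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(dim(table) == c(2L, 2L), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0) {
    warning("empty table; p = 1")
    return(list(p = 1, table = table))
  }
  ht <- stats::fisher.test(table)
  list(p = unname(ht$p.value), table = table)
}
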