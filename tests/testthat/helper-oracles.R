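# Independent oracles used to cross-check the package's statistics and
# detection machinery. These deliberately avoid the code paths they
# verify: direct formula evaluation, hypergeometric enumeration, and
# naive substring search.

# Yates-corrected chi-square for a 2x2 table, by the textbook formula
# n * (|ad - bc| - n/2)^2 / (r1 r2 c1 c2), floored at zero.
oracle_yates_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- max(0, abs(a * d - b * c) - n / 2)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Two-sided Fisher p by full hypergeometric enumeration with the
# minimum-likelihood rule.
oracle_fisher_two_sided <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by the definitional cumulative minimum.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / (m:1)))
  adj[order(o)]
}

# Exact two-sided rank-sum p for tie-free samples by full enumeration of
# all assignments of the pooled values to the two groups.
oracle_rank_sum <- function(x, y) {
  stopifnot(!anyDuplicated(c(x, y)))
  pooled <- c(x, y)
  m <- length(x)
  idx <- utils::combn(length(pooled), m)
  u_of <- function(xs) sum(outer(xs, setdiff(pooled, xs), ">"))
  u_all <- apply(idx, 2, function(i) u_of(pooled[i]))
  u_obs <- u_of(x)
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Naive presence check: does `s` (or its reverse complement) occur in
# every query genome of the cohort?
oracle_present_everywhere <- function(s, cohort, both = TRUE) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  all(vapply(cohort$queries, function(q) {
    any(grepl(s, q, fixed = TRUE)) ||
      (both && any(grepl(rc, q, fixed = TRUE)))
  }, logical(1)))
}
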