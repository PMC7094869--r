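#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped and ties receive mid-ranks. For n <= 25 the
#' p-value is exact, computed from the distribution of the positive-rank
#' sum over all 2^n sign assignments (by convolution, so mid-ranks are
#' handled exactly); above that a normal approximation with continuity and
#' tie correction is used.
#'
#' @param diffs numeric paired differences.
#' @param alternative `"two.sided"` (default), `"greater"` (positive shift)
#'   or `"less"`.
#' @param exact_limit largest n for the exact distribution (default 25).
#' @return p-value; 1 when all differences are zero.
#' @export
wilcoxon_signed_rank <- function(diffs, alternative = c("two.sided", "greater", "less"),
                                 exact_limit = 25) {
  alternative <- match.arg(alternative)
  d <- diffs[diffs != 0 & !is.na(diffs)]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])

  if (n <= exact_limit) {
    # exact null distribution of 2*W+ (2r is integral even with mid-ranks)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (ri in r2) {
      g <- numeric(total + 1)
      g[seq_len(total + 1 - ri) + ri] <- f[seq_len(total + 1 - ri)]
      f <- (f + g) / 2
    }
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(total + 1)])
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    return(p)
  }

  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  sigma <- sqrt(sigma2)
  z_ge <- (w - mu - 0.5) / sigma
  z_le <- (w - mu + 0.5) / sigma
  switch(alternative,
         two.sided = min(1, 2 * min(stats::pnorm(z_le), stats::pnorm(z_ge, lower.tail = FALSE))),
         greater = stats::pnorm(z_ge, lower.tail = FALSE),
         less = stats::pnorm(z_le))
}

#' Two-sample Student's t-test p-value
#'
#' Equal-variance two-sided two-sample t-test (Welch available via
#' `var_equal = FALSE`). When both groups have zero variance the p-value is
#' 1 for equal means and 0 otherwise.
#'
#' @param group_a,group_b numeric replicate values (>= 2 each).
#' @param var_equal pool the variance (default `TRUE`).
#' @return two-sided p-value.
#' @export
students_t <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("both groups need >= 2 replicates")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    return(if (mean(group_a) == mean(group_b)) 1 else 0)
  }
  t.test(group_a, group_b, var.equal = var_equal)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (`stats::p.adjust`, method
#' `"BH"`); stable under permutation of the input.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Log2 fold change with a pseudocount
#'
#' @param a,b non-negative abundances (condition A baseline, condition B
#'   numerator).
#' @param pseudocount added to both before the ratio (default 1).
#' @return `log2((b + pseudocount) / (a + pseudocount))`.
#' @export
log2_fold_change <- function(a, b, pseudocount = 1.0) {
  if (any(a < 0) || any(b < 0)) abort("abundances must be >= 0")
  log2((b + pseudocount) / (a + pseudocount))
}
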