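# Internal helpers shared across modules.

# Derive an independent sub-seed from a master seed so that each logical
# generation block (subjects, panel, hemolysis, ...) draws from its own RNG
# stream: adding a block never perturbs the draws of another. Kept < 2^31.
substream_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 48271 + 11 * offset) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Welch two-sample t statistic from summary statistics
#'
#' Computes the unequal-variance (Welch) t statistic and its Satterthwaite
#' degrees of freedom from group means, standard deviations and sizes, as used
#' to check demographic contrasts reported only as summary tables.
#'
#' @param m1,m2 group means.
#' @param s1,s2 group standard deviations.
#' @param n1,n2 group sizes.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
welch_t_summary <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  t <- (m2 - m1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square for a 2x2 table
#'
#' Uncorrected Pearson chi-square from the four cell counts, for checking
#' categorical group contrasts recoverable from printed percentages and sizes.
#'
#' @param a,b first row counts; @param c,d second row counts.
#' @return list with `chi2`, `df` (1) and `p`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  chi2 <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, df = 1, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
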