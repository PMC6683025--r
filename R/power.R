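# Analytic power for two-sample Mendelian randomization with a binary
# outcome, via the non-centrality approximation: the IVW estimate of the log
# OR per SD has approximate variance 1 / (N * r2 * cf * (1 - cf)), so power
# at two-sided level alpha is
#   Phi( sqrt(N * r2 * cf * (1 - cf)) * |log OR| - z_{1 - alpha/2} ).

#' Power of a two-sample MR analysis with a binary outcome
#'
#' @param n_total Outcome-GWAS sample size (cases + non-cases).
#' @param case_fraction Proportion of cases in the outcome GWAS, in (0, 1).
#' @param r2_exposure Proportion of exposure variance explained by the
#'   instrument set, in \[0, 1); for multi-SNP instruments the sum of
#'   per-SNP values (see [instrument_r2()]). Zero returns the no-information
#'   power `alpha/2` rather than erroring.
#' @param or_alternative Detectable odds ratio per 1 SD of exposure; power is
#'   symmetric in `or` vs `1/or`.
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @return Power in (0, 1). All arguments are vectorized.
#' @export
#' @examples
#' mr_power(588190, 65446 / 588190, r2_exposure = 0.021, or_alternative = 0.9)
mr_power <- function(n_total, case_fraction, r2_exposure, or_alternative,
                     alpha = 0.05) {
  stopifnot(
    all(n_total > 0), all(case_fraction > 0 & case_fraction < 1),
    all(r2_exposure >= 0 & r2_exposure < 1), all(or_alternative > 0),
    all(alpha > 0 & alpha < 1)
  )
  ncp <- sqrt(n_total * r2_exposure * case_fraction * (1 - case_fraction)) *
    abs(log(or_alternative))
  pnorm(ncp - qnorm(1 - alpha / 2))
}

#' Instrument-set variance explained from an association table
#'
#' Sums the per-SNP variance-explained values of one exposure's instruments.
#' Published tables often give a range per SNP; `reduce` picks the point
#' value used from each `[lo, hi]` interval (midpoint by default, since a
#' single published figure rarely states which bound it used).
#'
#' @param data Association rows for a single exposure.
#' @param reduce `"midpoint"`, `"lower"` or `"upper"`.
#' @return Proportion of variance explained (fraction, not percent).
#' @export
instrument_r2 <- function(data, reduce = c("midpoint", "lower", "upper")) {
  reduce <- match.arg(reduce)
  pct <- switch(reduce,
    midpoint = (data$var_exp_lo + data$var_exp_hi) / 2,
    lower = data$var_exp_lo,
    upper = data$var_exp_hi
  )
  sum(pct) / 100
}
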