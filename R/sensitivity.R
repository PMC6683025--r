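# Leave-one-out sensitivity analysis and the two-tier significance
# classification (Bonferroni-corrected for the ten fatty acids tested).

#' Leave-one-out inverse-variance-weighted analysis
#'
#' Repeats the fixed-effects IVW pooling with each instrument omitted in
#' turn, exposing estimates driven by a single SNP (for example one strongly
#' associated with the outcome in its own right).
#'
#' @inheritParams mr_ivw
#' @return A tibble with one row per omitted instrument, in input order:
#'   `omitted_rsid` followed by the [mr_ivw()] result columns computed on the
#'   remaining `k - 1` instruments.
#' @export
#' @examples
#' la <- dplyr::filter(fa_af_associations(), exposure == "linoleic acid")
#' mr_leave_one_out(wald_ratios(la, sd_scale = 2.69))
mr_leave_one_out <- function(ratios) {
  k <- nrow(ratios)
  if (k < 2) abort("leave-one-out requires at least 2 instruments")
  purrr::map_dfr(seq_len(k), function(i) {
    dplyr::bind_cols(
      tibble::tibble(omitted_rsid = ratios$rsid[i]),
      mr_ivw(ratios[-i, ], effects = "fixed")
    )
  })
}

#' Significance tier of an association
#'
#' Classifies two-sided p-values against the multiplicity-corrected
#' threshold used for ten exposures: `p < alpha_strict` (default 0.005,
#' i.e. 0.05/10) is `"significant"`, `alpha_strict <= p < alpha_nominal`
#' (default 0.05) is `"suggestive"` evidence, and anything else `"null"`.
#' Both boundaries belong to the weaker tier.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param alpha_strict Corrected significance threshold.
#' @param alpha_nominal Nominal threshold below which evidence is suggestive.
#' @return Character vector: `"significant"`, `"suggestive"` or `"null"`.
#' @export
classify_significance <- function(p, alpha_strict = 0.005, alpha_nominal = 0.05) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("`p` must lie in (0, 1]")
  }
  dplyr::case_when(
    p < alpha_strict ~ "significant",
    p < alpha_nominal ~ "suggestive",
    TRUE ~ "null"
  )
}
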