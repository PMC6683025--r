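# Seeded generator of two-sample summary statistics with known ground truth,
# emulating the structure of the bundled instrument table: per-SNP exposure
# betas with stated SEs, outcome betas under a configurable causal slope plus
# optional horizontal pleiotropy, and the same tabular dialect as real input.

#' Simulate a two-sample MR summary-statistic table
#'
#' Per SNP `i`, the exposure beta is drawn uniformly from
#' `exposure_beta_range` (bounded away from zero so no Wald ratio
#' degenerates), a pleiotropic outcome effect `alpha_i` is attached according
#' to `pleiotropy` (`"none"`: 0; `"balanced"`: `pleiotropy_scale` with random
#' sign; `"directional"`: `+pleiotropy_scale`), and the outcome beta is
#' `beta_causal * beta_exp_i + alpha_i + Normal(0, se_outcome)`. Reported
#' standard errors equal the generating ones; exposure betas are reported
#' without error by default, mirroring the first-order Wald convention
#' (`exposure_noise = TRUE` adds `Normal(0, se_exposure)` measurement error
#' for exercising the delta-method SE). With `pleiotropy = "none"` and
#' `se_outcome = 0` every Wald ratio equals `beta_causal * sd_scale` exactly.
#'
#' @param k Number of instruments (>= 1).
#' @param beta_causal True causal effect, log OR of outcome per unit of
#'   exposure (per % total fatty acids); the per-SD truth is
#'   `beta_causal * sd_scale`.
#' @param pleiotropy `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_scale Magnitude of each pleiotropic effect (log OR per
#'   allele), >= 0.
#' @param prop_pleiotropic Fraction of instruments given a pleiotropic effect
#'   (default 1; the affected subset is drawn at random).
#' @param exposure_beta_range Positive interval the exposure betas are drawn
#'   from (% total fatty acids per allele).
#' @param se_exposure,se_outcome Reported (and generating) standard errors.
#' @param sd_scale SD scale factor of the synthetic exposure.
#' @param exposure_noise Report exposure betas with measurement error?
#' @param seed Integer seed; identical seeds give byte-identical tables. The
#'   caller's RNG state is preserved.
#' @return An object of class `mr_simulation`: a list with `table` (an
#'   association tibble for one exposure named `"synthetic exposure"`) and
#'   `truth` (the configuration plus the realized per-SNP pleiotropy
#'   `alpha`, true exposure betas, and `beta_sd = beta_causal * sd_scale`).
#' @export
#' @examples
#' sim <- simulate_mr_data(k = 10, beta_causal = -0.02, seed = 7)
#' mr_ivw(wald_ratios(sim$table, sim$truth$sd_scale))
simulate_mr_data <- function(k,
                             beta_causal = 0,
                             pleiotropy = c("none", "balanced", "directional"),
                             pleiotropy_scale = 0,
                             prop_pleiotropic = 1,
                             exposure_beta_range = c(0.1, 0.5),
                             se_exposure = 0.005,
                             se_outcome = 0.008,
                             sd_scale = 1,
                             exposure_noise = FALSE,
                             seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k)) {
    abort("`k` must be a positive integer")
  }
  if (pleiotropy_scale < 0 || se_exposure < 0 || se_outcome < 0 || sd_scale <= 0) {
    abort("scales and standard errors must be non-negative (sd_scale > 0)")
  }
  if (length(exposure_beta_range) != 2 || any(exposure_beta_range <= 0) ||
      exposure_beta_range[1] > exposure_beta_range[2]) {
    abort("`exposure_beta_range` must be an increasing positive interval")
  }
  if (prop_pleiotropic < 0 || prop_pleiotropic > 1) {
    abort("`prop_pleiotropic` must lie in [0, 1]")
  }

  with_local_seed(seed, {
    beta_exp_true <- runif(k, exposure_beta_range[1], exposure_beta_range[2])
    n_pleio <- round(prop_pleiotropic * k)
    affected <- seq_len(k) %in% sample(seq_len(k), n_pleio)
    alpha <- switch(pleiotropy,
      none = rep(0, k),
      balanced = ifelse(affected, pleiotropy_scale * sample(c(-1, 1), k, replace = TRUE), 0),
      directional = ifelse(affected, pleiotropy_scale, 0)
    )
    beta_out <- beta_causal * beta_exp_true + alpha +
      if (se_outcome > 0) rnorm(k, 0, se_outcome) else 0
    beta_exp <- beta_exp_true +
      if (exposure_noise && se_exposure > 0) rnorm(k, 0, se_exposure) else 0

    alleles <- t(vapply(seq_len(k), function(i) sample(valid_alleles, 2),
                        character(2)))
    se_exp_rep <- rep(max(se_exposure, .Machine$double.eps), k)
    p_exp <- p_text_from_z(beta_exp / se_exp_rep)
    p_out <- p_text_from_z(beta_out / pmax(se_outcome, .Machine$double.eps))

    tbl <- tibble::tibble(
      exposure = "synthetic exposure",
      rsid = sprintf("rs%06d", seq_len(k)),
      gene = "SIM",
      chr = rep_len(1:22, k),
      ea = alleles[, 1],
      nea = alleles[, 2],
      beta_exp = beta_exp,
      se_exp = se_exp_rep,
      p_exp = p_exp$text,
      beta_out = beta_out,
      se_out = rep(se_outcome, k),
      p_out = p_out$text,
      var_explained_pct = "0.5"
    )
    tbl <- derive_assoc_columns(tbl)
    if (se_outcome > 0) validate_association_table(tbl)

    structure(
      list(
        table = tbl,
        truth = list(
          k = as.integer(k), beta_causal = beta_causal,
          beta_sd = beta_causal * sd_scale,
          pleiotropy = pleiotropy, pleiotropy_scale = pleiotropy_scale,
          prop_pleiotropic = prop_pleiotropic,
          alpha = alpha, beta_exp_true = beta_exp_true,
          se_exposure = se_exposure, se_outcome = se_outcome,
          sd_scale = sd_scale, seed = seed
        )
      ),
      class = "mr_simulation"
    )
  })
}

#' @export
print.mr_simulation <- function(x, ...) {
  cat(sprintf(
    "<mr_simulation> k = %d, beta_causal = %g (per SD: %g), pleiotropy = %s\n",
    x$truth$k, x$truth$beta_causal, x$truth$beta_sd, x$truth$pleiotropy
  ))
  print(x$table, ...)
  invisible(x)
}
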