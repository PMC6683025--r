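# Causal estimators for two-sample summary-data Mendelian randomization:
# per-SNP Wald ratios on the per-SD scale, inverse-variance-weighted pooling
# under fixed and multiplicative random effects, the weighted-median
# estimator, and MR-Egger regression. All estimators are pure functions of
# in-memory tibbles.

# Evaluate `code` with the RNG seeded locally, restoring the caller's RNG
# state afterwards so estimator calls never perturb a user's stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# One-row pooled-result tibble shared by every estimator. `ci_log_scale`
# keeps the Egger intercept's interval on the log-odds scale.
new_mr_result <- function(method, k, estimate, se,
                          p = NULL, crit = qnorm(0.975),
                          q_stat = NA_real_, q_df = NA_integer_,
                          q_p = NA_real_, i2_pct = NA_real_, phi = NA_real_,
                          ci_log_scale = FALSE, note = NA_character_) {
  if (is.null(p)) p <- 2 * pnorm(-abs(estimate / se))
  lo <- estimate - crit * se
  hi <- estimate + crit * se
  tibble::tibble(
    method = method, k = as.integer(k),
    estimate = estimate, se = se, or = exp(estimate),
    ci_low = if (ci_log_scale) lo else exp(lo),
    ci_high = if (ci_log_scale) hi else exp(hi),
    p = p, q_stat = q_stat, q_df = as.integer(q_df), q_p = q_p,
    i2_pct = i2_pct, phi = phi, note = note
  )
}

#' Per-SNP Wald ratio estimates on the per-SD scale
#'
#' The Wald ratio divides each SNP's outcome association (log OR per
#' effect-allele copy) by its exposure association (% total fatty acids per
#' copy) and rescales by the exposure's SD so every estimate is a log OR per
#' 1 SD of exposure. The default standard error is first order,
#' `se_out / |beta_exp| * sd_scale`, the convention of summary-data MR, which
#' treats the exposure beta as measured without error; `se_method = "delta"`
#' adds the exposure-beta uncertainty term.
#'
#' @param data Association rows for a single exposure (see [assoc_columns()]).
#' @param sd_scale Positive scalar, % total fatty acids per 1 SD of exposure.
#' @param se_method `"first_order"` (default) or `"delta"`.
#' @return A tibble with columns `rsid`, `estimate`, `se`, `weight`
#'   (`weight = 1/se^2`), one row per SNP in input order.
#' @export
#' @examples
#' la <- dplyr::filter(fa_af_associations(), exposure == "linoleic acid")
#' wald_ratios(la, sd_scale = 2.69)
wald_ratios <- function(data, sd_scale, se_method = c("first_order", "delta")) {
  se_method <- match.arg(se_method)
  if (!is.numeric(sd_scale) || length(sd_scale) != 1 || sd_scale <= 0) {
    abort("`sd_scale` must be a positive scalar")
  }
  if (any(data$beta_exp == 0)) {
    abort(sprintf("undefined Wald ratio: beta_exp is 0 for %s",
                  paste(data$rsid[data$beta_exp == 0], collapse = ", ")))
  }
  est <- data$beta_out / data$beta_exp * sd_scale
  se <- if (se_method == "first_order") {
    data$se_out / abs(data$beta_exp) * sd_scale
  } else {
    sqrt(data$se_out^2 / data$beta_exp^2 +
           data$beta_out^2 * data$se_exp^2 / data$beta_exp^4) * sd_scale
  }
  tibble::tibble(rsid = data$rsid, estimate = est, se = se, weight = 1 / se^2)
}

#' Inverse-variance-weighted pooled estimate
#'
#' Pools per-SNP Wald ratios with weights `1/se^2`. The fixed-effects
#' standard error is `1/sqrt(sum(w))`; the multiplicative random-effects
#' model keeps the same point estimate and inflates the fixed SE by
#' `sqrt(phi)` with `phi = max(1, Q/(k-1))`, where Q is Cochran's
#' heterogeneity statistic on k-1 degrees of freedom. `I2 = max(0,
#' 100*(Q - df)/Q)` summarises the share of variation beyond chance.
#' Confidence intervals use the normal 1.96 critical value and are reported
#' on the odds-ratio scale.
#'
#' @param ratios A Wald-ratio tibble from [wald_ratios()] (columns `rsid`,
#'   `estimate`, `se`).
#' @param effects `"fixed"` or `"random"` (multiplicative). Random effects
#'   with a single instrument falls back to fixed with a note.
#' @return A one-row result tibble: `method`, `k`, `estimate`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`, `q_stat`, `q_df`, `q_p`, `i2_pct`, `phi`,
#'   `note`.
#' @export
mr_ivw <- function(ratios, effects = c("fixed", "random")) {
  effects <- match.arg(effects)
  k <- nrow(ratios)
  if (k < 1) abort("at least one Wald ratio is required")
  if (any(!is.finite(ratios$estimate))) abort("non-finite Wald ratio estimate")
  note <- NA_character_

  if (any(ratios$se == 0)) {
    # exact (zero-SE) instruments: defined only when they agree
    exact <- ratios$estimate[ratios$se == 0]
    if (length(unique(exact)) > 1) {
      abort("conflicting exact (zero-SE) Wald ratios")
    }
    return(new_mr_result(paste0("ivw_", effects), k, exact[1], 0, p = NA_real_,
                         note = "exact instruments (zero SE)"))
  }

  w <- 1 / ratios$se^2
  est <- sum(w * ratios$estimate) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  if (k >= 2) {
    q <- sum(w * (ratios$estimate - est)^2)
    q_df <- k - 1L
    q_p <- pchisq(q, df = q_df, lower.tail = FALSE)
    i2 <- max(0, 100 * (q - q_df) / q)
    if (q == 0) i2 <- 0
    phi <- max(1, q / q_df)
  } else {
    q <- NA_real_; q_df <- NA_integer_; q_p <- NA_real_
    i2 <- NA_real_; phi <- NA_real_
  }

  if (effects == "random" && k < 2) {
    effects <- "fixed"
    note <- "k < 2: random effects fell back to fixed"
  }
  se <- if (effects == "random") se_fixed * sqrt(phi) else se_fixed
  new_mr_result(paste0("ivw_", effects), k, est, se,
                q_stat = q, q_df = q_df, q_p = q_p, i2_pct = i2, phi = phi,
                note = note)
}

# Weighted-median point estimate: order ratios (ties broken by rsid), take
# cumulative-weight percentiles p_j = (S_j - w_j/2)/S_total and linearly
# interpolate the ratio at p = 0.5 (clamped at the extreme ratios).
weighted_median_point <- function(estimate, weight, rsid = NULL) {
  ord <- if (is.null(rsid)) order(estimate) else order(estimate, rsid)
  r <- estimate[ord]
  w <- weight[ord]
  s <- cumsum(w)
  p <- (s - w / 2) / sum(w)
  if (length(r) == 1) return(r)
  approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted median is the Wald ratio at the 50th weighted percentile of
#' the ordered per-SNP ratios; it is consistent when at least half the total
#' weight comes from valid instruments, making it robust to a minority of
#' pleiotropic SNPs. The point estimate is deterministic; its standard error
#' is estimated by a parametric bootstrap that redraws each ratio from
#' `Normal(estimate_i, se_i)` (weights held at their observed values) and
#' takes the standard deviation of the replicated medians. p-value and CI
#' use the normal approximation.
#'
#' @inheritParams mr_ivw
#' @param n_boot Number of bootstrap replicates (default 10000; fewer than
#'   100 is flagged in `note`).
#' @param seed Optional integer seed for the bootstrap; the caller's RNG
#'   state is preserved.
#' @return A one-row result tibble (see [mr_ivw()]); heterogeneity columns
#'   are `NA`.
#' @export
mr_weighted_median <- function(ratios, n_boot = 10000, seed = NULL) {
  k <- nrow(ratios)
  if (k < 3) abort("weighted median requires at least 3 instruments")
  if (n_boot < 1) abort("`n_boot` must be a positive integer")
  est <- weighted_median_point(ratios$estimate, 1 / ratios$se^2, ratios$rsid)
  boot <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      r_star <- rnorm(k, mean = ratios$estimate, sd = ratios$se)
      weighted_median_point(r_star, 1 / ratios$se^2, ratios$rsid)
    }, numeric(1))
  })
  note <- if (n_boot < 100) "n_boot < 100: bootstrap SE unreliable" else NA_character_
  new_mr_result("weighted_median", k, est, sd(boot), note = note)
}

#' MR-Egger regression
#'
#' Weighted least squares of per-allele outcome betas on per-allele exposure
#' betas with weights `1/se_out^2` and a free intercept, after orienting
#' every SNP so its exposure beta is positive. The slope, rescaled to log OR
#' per 1 SD, is a pleiotropy-corrected causal estimate; the intercept (log OR
#' per allele, unscaled) estimates the average directional pleiotropy, and
#' its two-sided test is the directional-pleiotropy test. Standard errors
#' use a multiplicative overdispersion model with the residual scale
#' `phi = max(1, RSS_w/(k-2))`; inference is normal (z), matching the Stata
#' summary-MR implementations this reproduces.
#'
#' @param data Association rows for a single exposure (k >= 3 SNPs).
#' @param sd_scale Positive scalar, % total fatty acids per 1 SD.
#' @return A two-row result tibble: methods `egger_slope` (OR-scale CI per
#'   SD) and `egger_intercept` (estimate and CI on the per-allele log-OR
#'   scale).
#' @export
mr_egger <- function(data, sd_scale) {
  k <- nrow(data)
  if (k < 3) abort("MR-Egger requires at least 3 instruments")
  if (!is.numeric(sd_scale) || length(sd_scale) != 1 || sd_scale <= 0) {
    abort("`sd_scale` must be a positive scalar")
  }
  neg <- data$beta_exp < 0
  x <- ifelse(neg, -data$beta_exp, data$beta_exp)
  y <- ifelse(neg, -data$beta_out, data$beta_out)
  w <- 1 / data$se_out^2

  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  sxx <- sum(w * (x - xb)^2)
  if (sxx == 0) abort("collinear instruments: all exposure betas equal after orientation")
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  rss <- sum(w * (y - intercept - slope * x)^2)
  phi <- max(1, rss / (k - 2))
  se_slope <- sqrt(phi / sxx)
  se_int <- sqrt(phi * (1 / sum(w) + xb^2 / sxx))

  dplyr::bind_rows(
    new_mr_result("egger_slope", k, slope * sd_scale, se_slope * sd_scale,
                  phi = phi),
    new_mr_result("egger_intercept", k, intercept, se_int,
                  phi = phi, ci_log_scale = TRUE)
  )
}
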