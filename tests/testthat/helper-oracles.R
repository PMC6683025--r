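# Independent brute-force oracles, written directly from the defining
# formulas with no shared code with the package internals.

oracle_ivw <- function(est, se, effects = "fixed") {
  w <- 1 / se^2
  mu <- sum(w * est) / sum(w)
  se_f <- sqrt(1 / sum(w))
  q <- sum(w * (est - mu)^2)
  phi <- max(1, q / (length(est) - 1))
  list(estimate = mu,
       se = if (effects == "fixed") se_f else se_f * sqrt(phi),
       q = q, phi = phi)
}

oracle_weighted_median <- function(est, se) {
  ord <- order(est)
  r <- est[ord]
  w <- (1 / se^2)[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  j <- max(which(p <= 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

# toy ratio tibble for unit tests
make_ratios <- function(est, se, rsid = sprintf("rs%03d", seq_along(est))) {
  tibble::tibble(rsid = rsid, estimate = est, se = se, weight = 1 / se^2)
}

fixture_rows <- function(name) {
  dplyr::filter(fa_af_associations(), exposure == name)
}
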