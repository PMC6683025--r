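test_that("Wald ratios scale betas per SD with first-order SEs", {
  la <- fixture_rows("linoleic acid")
  r <- wald_ratios(la, sd_scale = 2.69)
  jm <- r[r$rsid == "rs10740118", ]
  expect_equal(jm$estimate, -0.047 / 0.25 * 2.69)
  expect_equal(jm$estimate, -0.50572, tolerance = 1e-6)
  expect_equal(jm$se, 0.007 / 0.25 * 2.69)
  expect_equal(jm$se, 0.07532, tolerance = 1e-6)
  expect_equal(r$weight, 1 / r$se^2)

  # zero numerator: estimate 0, SE untouched by the numerator
  rec <- la[1, ]
  rec$beta_out <- 0
  r0 <- wald_ratios(rec, 2.69)
  expect_equal(r0$estimate, 0)
  expect_equal(r0$se, jm$se)

  # identity scaling
  rec$beta_exp <- 1
  rec$beta_out <- 0.123
  r1 <- wald_ratios(rec, 1)
  expect_equal(r1$estimate, 0.123)
  expect_equal(r1$se, rec$se_out)

  rec$beta_exp <- 0
  expect_error(wald_ratios(rec, 2.69), "undefined")
  expect_error(wald_ratios(la, -1), "positive")

  # delta-method SE adds the exposure-beta term
  rd <- wald_ratios(la, 2.69, se_method = "delta")
  rf <- wald_ratios(la, 2.69)
  expect_true(all(rd$estimate == rf$estimate))
  expect_true(all(rd$se > rf$se))
  expect_equal(rd$se,
               sqrt(la$se_out^2 / la$beta_exp^2 +
                      la$beta_out^2 * la$se_exp^2 / la$beta_exp^4) * 2.69)
})

test_that("IVW pooling matches its degenerate and identity cases", {
  one <- make_ratios(-0.4, 0.1)
  res <- mr_ivw(one)
  expect_equal(res$estimate, -0.4)
  expect_equal(res$se, 0.1)
  expect_equal(res$k, 1L)

  # random effects with k = 1 falls back to fixed with a note
  r1 <- mr_ivw(one, "random")
  expect_equal(r1$method, "ivw_fixed")
  expect_match(r1$note, "fell back")

  # equal ratios: no heterogeneity
  eq <- make_ratios(rep(0.2, 4), rep(0.05, 4))
  req <- mr_ivw(eq)
  expect_equal(req$estimate, 0.2)
  expect_equal(req$q_stat, 0)
  expect_equal(req$i2_pct, 0)
  expect_equal(req$phi, 1)
  expect_equal(mr_ivw(eq, "random")$se, req$se)

  expect_error(mr_ivw(make_ratios(numeric(0), numeric(0))), "at least one")
  expect_error(mr_ivw(make_ratios(c(0, Inf), c(1, 1))), "non-finite")
})

test_that("IVW agrees with brute-force and library oracles", {
  set.seed(41)
  for (i in 1:1000) {
    k <- sample(2:4, 1)
    est <- rnorm(k, 0, 0.5)
    se <- runif(k, 0.01, 0.3)
    rat <- make_ratios(est, se)
    o <- oracle_ivw(est, se)
    f <- mr_ivw(rat)
    expect_equal(f$estimate, o$estimate)
    expect_equal(f$se, o$se)
    expect_equal(f$q_stat, o$q)
    r <- mr_ivw(rat, "random")
    expect_equal(r$estimate, o$estimate)
    expect_equal(r$se, oracle_ivw(est, se, "random")$se)
    expect_true(r$se >= f$se)
    if (f$q_stat <= f$q_df) expect_equal(r$se, f$se)
  }
  # cross-check against metafor's fixed-effect meta-analysis on the fixture
  skip_if_not_installed("metafor")
  ex <- fa_exposures()
  for (i in which(ex$k >= 2)) {
    rat <- wald_ratios(ex$instruments[[i]], ex$sd_scale[i])
    ref <- metafor::rma(yi = rat$estimate, sei = rat$se, method = "FE")
    got <- mr_ivw(rat)
    expect_equal(got$estimate, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(got$se, ref$se, tolerance = 1e-10)
    expect_equal(got$q_stat, ref$QE, tolerance = 1e-10)
  }
})

test_that("IVW equals weighted regression through the origin", {
  ex <- fa_exposures()
  for (i in which(ex$k >= 2)) {
    ins <- ex$instruments[[i]]
    fit <- lm(beta_out ~ 0 + beta_exp, data = ins, weights = 1 / ins$se_out^2)
    ivw <- mr_ivw(wald_ratios(ins, ex$sd_scale[i]))
    expect_equal(ivw$estimate, unname(coef(fit)[1]) * ex$sd_scale[i],
                 tolerance = 1e-12)
  }
})

test_that("weighted median interpolates the 50th weighted percentile", {
  # equal weights, odd k: the plain median
  odd <- make_ratios(c(0.3, -0.1, 0.7, 0.1, -0.5), rep(0.2, 5))
  expect_equal(mr_weighted_median(odd, n_boot = 200, seed = 1)$estimate,
               median(odd$estimate))

  # brute-force oracle over random small problems (point estimate)
  set.seed(42)
  for (i in 1:1000) {
    k <- sample(3:4, 1)
    est <- rnorm(k)
    se <- runif(k, 0.05, 0.5)
    rat <- make_ratios(est, se)
    expect_equal(mr_weighted_median(rat, n_boot = 1, seed = 1)$estimate,
                 oracle_weighted_median(est, se))
  }

  # a dominant ratio pulls the estimate into its adjacent interval
  grid <- make_ratios(c(-1, 0, 1), c(1, 1, 1))
  dominant <- function(w2) {
    rat <- grid
    rat$weight <- c(1, w2, 1)
    rat$se <- 1 / sqrt(rat$weight)
    mr_weighted_median(rat, n_boot = 1, seed = 1)$estimate
  }
  expect_true(abs(dominant(3)) < 0.5)       # >50% of weight near 0
  expect_equal(dominant(1e6), 0, tolerance = 1e-3)  # weight -> 100%: that ratio

  expect_error(mr_weighted_median(make_ratios(c(1, 2), c(1, 1))), "at least 3")
  low <- mr_weighted_median(odd, n_boot = 50, seed = 1)
  expect_match(low$note, "n_boot")
})

test_that("weighted-median bootstrap SE is seed-reproducible and calibrated", {
  rat <- make_ratios(c(-0.4, -0.1, 0.05), c(0.08, 0.02, 0.06))
  a <- mr_weighted_median(rat, n_boot = 500, seed = 99)
  b <- mr_weighted_median(rat, n_boot = 500, seed = 99)
  expect_identical(a, b)
  c2 <- mr_weighted_median(rat, n_boot = 500, seed = 100)
  expect_false(isTRUE(all.equal(a$se, c2$se)))
  # estimator calls never disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(mr_weighted_median(rat, n_boot = 50, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("MR-Egger recovers exact linear data and flags degenerate input", {
  base <- fixture_rows("stearic acid")  # 3 SNPs, convenient shell
  # exact proportional data: slope = c * sd, intercept = 0
  lin <- base
  lin$beta_out <- 0.3 * lin$beta_exp
  eg <- mr_egger(lin, sd_scale = 2)
  expect_equal(eg$estimate[eg$method == "egger_slope"], 0.6, tolerance = 1e-12)
  expect_equal(eg$estimate[eg$method == "egger_intercept"], 0, tolerance = 1e-12)

  # constant outcome: slope 0, intercept the constant
  flat <- base
  flat$beta_exp <- c(0.1, 0.2, 0.3)
  flat$beta_out <- rep(0.05, 3)
  ef <- mr_egger(flat, 1)
  expect_equal(ef$estimate[ef$method == "egger_slope"], 0, tolerance = 1e-12)
  expect_equal(ef$estimate[ef$method == "egger_intercept"], 0.05, tolerance = 1e-12)

  # pleiotropy alpha + slope beta recovered exactly without noise
  lin2 <- base
  lin2$beta_exp <- c(0.1, 0.25, 0.4)
  lin2$beta_out <- 0.02 + (-0.15) * lin2$beta_exp
  e2 <- mr_egger(lin2, 1)
  expect_equal(e2$estimate, c(-0.15, 0.02), tolerance = 1e-12)

  expect_error(mr_egger(base[1:2, ], 1), "at least 3")
  coll <- base
  coll$beta_exp <- rep(0.2, 3)
  expect_error(mr_egger(coll, 1), "collinear")
})

test_that("MR-Egger matches a weighted least-squares oracle with multiplicative scale", {
  la <- fixture_rows("linoleic acid")
  fit <- lm(beta_out ~ beta_exp, data = la, weights = 1 / la$se_out^2)
  phi <- max(1, sum((1 / la$se_out^2) * resid(fit)^2) / (nrow(la) - 2))
  co <- coef(summary(fit))
  se_unscaled <- co[, 2] / summary(fit)$sigma  # remove lm's estimated scale
  eg <- mr_egger(la, 2.69)
  expect_equal(eg$estimate[eg$method == "egger_slope"], co[2, 1] * 2.69,
               tolerance = 1e-10)
  expect_equal(eg$se[eg$method == "egger_slope"],
               se_unscaled[2] * sqrt(phi) * 2.69, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(eg$estimate[eg$method == "egger_intercept"], co[1, 1],
               tolerance = 1e-10)
  expect_equal(eg$se[eg$method == "egger_intercept"],
               se_unscaled[1] * sqrt(phi), tolerance = 1e-10,
               ignore_attr = TRUE)
  # directional-pleiotropy test for linoleic acid is null, near the
  # published 0.22 (rounded inputs preclude an exact match)
  p_int <- eg$p[eg$method == "egger_intercept"]
  expect_equal(p_int, 0.22, tolerance = 0.5)
  expect_gt(p_int, 0.05)
})

test_that("all estimators are invariant under re-orientation of any subset", {
  la <- fixture_rows("linoleic acid")
  flipped <- harmonize_alleles(la, c(rs174547 = "T", rs16966952 = "A"))
  r0 <- wald_ratios(la, 2.69)
  r1 <- wald_ratios(flipped, 2.69)
  expect_equal(mr_ivw(r1), mr_ivw(r0))
  expect_equal(mr_ivw(r1, "random"), mr_ivw(r0, "random"))
  expect_equal(mr_weighted_median(r1, n_boot = 200, seed = 5),
               mr_weighted_median(r0, n_boot = 200, seed = 5))
  expect_equal(mr_egger(flipped, 2.69), mr_egger(la, 2.69))
})
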