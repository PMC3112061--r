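# The DAE estimator, criteria, NMD classification and mixing fit.

test_that("identical cDNA and gDNA ratios give a null estimate", {
  r <- c(0.8, 0.82, 0.78, 0.8)
  res <- call_dae(dae_estimate(r, r))
  expect_equal(res$delta, 0)
  expect_equal(res$dae_percent, 0)
  expect_false(res$crit_magnitude)
  expect_false(res$call)
})

test_that("the textbook example halves the ratio: delta ~ ln(0.5), dae ~ 50%", {
  g <- c(0.80, 0.82, 0.78, 0.80)
  cc <- c(0.40, 0.41, 0.39, 0.40)
  cfg <- assay_config(var_equal = TRUE)
  res <- dae_estimate(g, cc, cfg)
  want <- pooled_t_oracle(log(cc), log(g))
  expect_equal(res$delta, log(0.5), tolerance = 1e-3)
  expect_equal(res$dae_percent, 50, tolerance = 0.1)
  expect_equal(res$t_stat, want$t, tolerance = 1e-10)
  expect_equal(res$p_value, want$p, tolerance = 1e-10)
  expect_lt(res$p_value, 0.001)
  expect_equal(c(res$ci_low, res$ci_high), want$ci, tolerance = 1e-10)
})

test_that("both t flavours match independent textbook implementations to 1e-10", {
  set.seed(13)
  for (i in 1:50) {
    g <- exp(rnorm(4, 0, 0.2))
    cc <- exp(rnorm(4, -0.3, 0.35))
    pooled <- dae_estimate(g, cc, assay_config(var_equal = TRUE))
    op <- pooled_t_oracle(log(cc), log(g))
    expect_equal(pooled$p_value, op$p, tolerance = 1e-10)
    expect_equal(pooled$t_stat, op$t, tolerance = 1e-10)
    expect_equal(c(pooled$ci_low, pooled$ci_high), op$ci, tolerance = 1e-10)
    welch <- dae_estimate(g, cc, assay_config(var_equal = FALSE))
    ow <- welch_t_oracle(log(cc), log(g))
    expect_equal(welch$p_value, ow$p, tolerance = 1e-10)
    expect_equal(welch$df, ow$df, tolerance = 1e-8)
  }
})

test_that("degenerate zero-variance inputs take the documented branches", {
  same <- rep(1, 4)
  halved <- rep(0.5, 4)
  res <- dae_estimate(same, halved)
  expect_true(res$degenerate_variance)
  expect_equal(res$p_value, 0)
  expect_equal(c(res$ci_low, res$ci_high), rep(res$delta, 2))
  null <- dae_estimate(same, same)
  expect_true(null$degenerate_variance)
  expect_equal(null$p_value, 1)
})

test_that("fewer than two replicates in either group errors", {
  expect_error(dae_estimate(1, c(0.5, 0.5)), "2")
  expect_error(dae_estimate(c(1, 1), 0.5), "2")
})

test_that("a noise-free carrier recovers the oracle dae_percent (~100 d minus cross-talk)", {
  cfg <- noiseless_cfg()
  for (d in c(0.2, 0.37, 0.5)) {
    res <- sim_individual_result(d = d, cfg = cfg)
    want <- oracle_dae_percent(d, kappa = cfg$kappa)
    expect_equal(res$dae_percent, want, tolerance = 0.02)
    # generative identity up to peak cross-talk (< 1.1 pp over this range)
    expect_lt(abs(res$dae_percent - 100 * d), 1.1)
  }
})

test_that("the three criteria combine exactly as specified", {
  cfg <- assay_config()
  mk <- function(dae, p, lo, hi) {
    r <- dae_estimate(c(1, 1.01, 0.99, 1), c(0.5, 0.51, 0.49, 0.5))
    r$dae_percent <- dae; r$p_value <- p; r$p_used <- p
    r$ci_low <- lo; r$ci_high <- hi
    call_dae(r, cfg)
  }
  expect_true(mk(50, 1e-6, -0.75, -0.63)$call)
  r <- mk(15, 0.01, -0.3, -0.1)              # magnitude fails
  expect_false(r$call); expect_false(r$crit_magnitude)
  expect_true(r$crit_pvalue); expect_true(r$crit_ci)
  r <- mk(25, 0.20, -0.4, -0.1)              # p-value fails
  expect_false(r$call); expect_false(r$crit_pvalue)
  r <- mk(25, 0.01, -0.4, 0.02)              # CI includes 0
  expect_false(r$call); expect_false(r$crit_ci)
})

test_that("NMD classification follows the rescue rules", {
  cfg <- assay_config()
  g <- c(1.00, 1.02, 0.98, 1.01)
  cc <- c(0.49, 0.51, 0.50, 0.48)            # strong imbalance -> call
  rescued <- c(0.97, 1.03, 1.00, 0.99)       # puromycin back to gDNA profile
  res <- dae_test(g, cc, puromycin = rescued, config = cfg)
  expect_true(res$call)
  expect_equal(res$nmd_class, "nmd_consistent")

  not_rescued <- cc * c(1.00, 0.99, 1.02, 0.99)
  res2 <- dae_test(g, cc, puromycin = not_rescued, config = cfg)
  expect_equal(res2$nmd_class, "regulatory_consistent")

  balanced <- c(0.99, 1.01, 1.02, 0.97)
  res3 <- dae_test(g, balanced, puromycin = rescued, config = cfg)
  expect_false(res3$call)
  expect_equal(res3$nmd_class, "no_dae")

  expect_warning(res4 <- nmd_assessment(call_dae(dae_estimate(g, cc, cfg), cfg),
                                        NULL, g, cfg),
                 "puromycin")
  expect_equal(res4$nmd_class, "indeterminate")
})

test_that("orientation invariance: inverting all ratios flips delta only", {
  set.seed(21)
  g <- exp(rnorm(4, -0.2, 0.05))
  cc <- exp(rnorm(4, -0.9, 0.12))
  a <- call_dae(dae_estimate(g, cc))
  b <- call_dae(dae_estimate(1 / g, 1 / cc))
  expect_equal(b$delta, -a$delta, tolerance = 1e-12)
  expect_equal(b$dae_percent, a$dae_percent, tolerance = 1e-12)
  expect_equal(abs(b$t_stat), abs(a$t_stat), tolerance = 1e-10)
  expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  expect_equal(b$crit_ci, a$crit_ci)
  expect_equal(b$call, a$call)
})

test_that("yield-bias invariance: a shared kappa factor cancels in the estimate", {
  set.seed(22)
  g <- exp(rnorm(4, 0, 0.05))
  cc <- exp(rnorm(4, -0.5, 0.1))
  base <- call_dae(dae_estimate(g, cc))
  for (k in c(0.5, 0.8, 1.25, 2)) {
    shifted <- call_dae(dae_estimate(k * g, k * cc))
    expect_equal(shifted$delta, base$delta, tolerance = 1e-12)
    expect_equal(shifted$dae_percent, base$dae_percent, tolerance = 1e-12)
    expect_equal(shifted$p_value, base$p_value, tolerance = 1e-10)
    expect_equal(shifted$call, base$call)
  }
})

test_that("end-to-end kappa invariance: probe yield bias never changes a call", {
  # same RNG draws under each kappa; noise-free so the cancellation is clean
  for (k in c(0.5, 0.8, 1.25, 2)) {
    cfg <- noiseless_cfg(kappa = k)
    res <- sim_individual_result(d = 0.5, cfg = cfg)
    expect_true(res$call)
    expect_equal(res$dae_percent, oracle_dae_percent(0.5, kappa = k),
                 tolerance = 0.02)
    null <- sim_individual_result(d = 0, cfg = cfg)
    expect_false(null$crit_magnitude)
  }
})

test_that("an exact mixing series fits the identity line", {
  expected <- seq(0.1, 0.9, 0.1)
  measured <- lapply(expected, function(f) rep(f / (1 - f), 4))
  fit <- mixing_series_fit(expected, measured)
  expect_equal(fit$slope, 1, tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_equal(coef(fit)[["slope"]], fit$slope)
  expect_equal(predict(fit, 0.25), 0.25, tolerance = 1e-6)
})

test_that("raw-ratio regression is available as the documented alternative", {
  expected <- seq(0.1, 0.9, 0.1)
  measured <- lapply(expected, function(f) rep(f / (1 - f), 4))
  fit <- mixing_series_fit(expected, measured,
                           assay_config(fraction_regression = FALSE))
  expect_equal(fit$slope, 1, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
})

test_that("mixing fits reject degenerate input and drop failed points", {
  expect_error(mixing_series_fit(c(0.3, 0.7), list(1, 2)), "3")
  expected <- c(0.2, 0.4, 0.6, 0.8)
  measured <- list(rep(0.25, 3), numeric(0), rep(1.5, 3), rep(4, 3))
  expect_warning(fit <- mixing_series_fit(expected, measured), "dropped")
  expect_equal(fit$n_points, 3L)
  measured2 <- list(rep(0.25, 3), numeric(0), NULL, rep(4, 3))
  expect_error(suppressWarnings(mixing_series_fit(expected, measured2)),
               "fewer than 3")
})
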