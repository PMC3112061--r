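# Independent oracles used across the suite. Deliberately written from first
# principles (closed forms, brute-force least squares, textbook t formulas),
# not via the package's own code paths.

# --- analytic two-logistic melt model ---------------------------------------
# F(T) = A * (a1 * plogis((tm1 - T)/s) + kappa * a2 * plogis((tm2 - T)/s))
# -dF/dT = (A/s) * (a1 * p1 (1 - p1) + kappa * a2 * p2 (1 - p2))
oracle_neg_dfdt <- function(a1, a2, kappa = 1, tm1 = 54, tm2 = 60, s = 1, A = 100) {
  function(T) {
    p1 <- stats::plogis((tm1 - T) / s)
    p2 <- stats::plogis((tm2 - T) / s)
    (A / s) * (a1 * p1 * (1 - p1) + kappa * a2 * p2 * (1 - p2))
  }
}

# Peak of the analytic derivative within a window (continuous optimum, no
# grid, no smoothing): the ground truth the pipeline should approach.
oracle_peak <- function(fn, window) {
  o <- stats::optimize(fn, interval = window, maximum = TRUE, tol = 1e-10)
  list(tm = o$maximum, h = o$objective)
}

oracle_ratio <- function(a1, a2, kappa = 1, tm1 = 54, tm2 = 60, s = 1, A = 100,
                         win1 = c(50, 57), win2 = c(57.5, 64)) {
  fn <- oracle_neg_dfdt(a1, a2, kappa, tm1, tm2, s, A)
  oracle_peak(fn, win2)$h / oracle_peak(fn, win1)$h
}

# Expected noise-free dae_percent for a carrier with degradation d under the
# default generative model (gDNA 1:1, cDNA allele 2 reduced by d).
oracle_dae_percent <- function(d, kappa = 0.8) {
  rg <- oracle_ratio(0.5, 0.5, kappa)
  rc <- oracle_ratio(0.5, 0.5 * (1 - d), kappa)
  100 * (1 - exp(-abs(log(rc) - log(rg))))
}

# --- brute-force Savitzky-Golay ---------------------------------------------
# Sliding centred least-squares polynomial fit; interior points only.
sg_bruteforce <- function(values, window, order, deriv = 0, step = 1) {
  n <- length(values)
  half <- (window - 1) / 2
  out <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    idx <- (i - half):(i + half)
    x <- (idx - i) * step
    fit <- stats::lm(values[idx] ~ stats::poly(x, order, raw = TRUE))
    cf <- stats::coef(fit)
    out[i] <- if (deriv == 0) cf[[1]] else cf[[2]]
  }
  out
}

# --- textbook two-sample t tests --------------------------------------------
pooled_t_oracle <- function(x, y, conf = 0.95) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- (mean(x) - mean(y)) / se
  df <- nx + ny - 2
  q <- stats::qt(1 - (1 - conf) / 2, df)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       ci = mean(x) - mean(y) + c(-1, 1) * q * se)
}

welch_t_oracle <- function(x, y, conf = 0.95) {
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x) / nx; vy <- stats::var(y) / ny
  se <- sqrt(vx + vy)
  t <- (mean(x) - mean(y)) / se
  df <- (vx + vy)^2 / (vx^2 / (nx - 1) + vy^2 / (ny - 1))
  q <- stats::qt(1 - (1 - conf) / 2, df)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
       ci = mean(x) - mean(y) + c(-1, 1) * q * se)
}
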