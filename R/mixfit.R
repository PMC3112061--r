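# Mixing-series calibration: titrations of the two opposite homozygotes in
# known proportions should give measured allelic fractions linear in the
# expected ones; the fit's R^2 summarizes assay linearity.

#' Fit the mixing-series calibration line
#'
#' For each mixture point the observed allele-2 fraction is the mean over
#' replicates of `ratio / (1 + ratio)` (i.e. `h2 / (h1 + h2)`); an ordinary
#' least-squares line of observed on expected fractions gives slope,
#' intercept and the determination coefficient R^2. With
#' `config$fraction_regression = FALSE` raw ratios `h2/h1` are regressed on
#' the expected ratios `f / (1 - f)` instead.
#'
#' @param expected Numeric vector of expected allele-2 fractions, in (0, 1),
#'   one per mixture point (at least 3 points).
#' @param measured Replicate measurements per point: a list (same length as
#'   `expected`) of numeric ratio vectors or `ratio_measurement` data.frames.
#'   Points whose replicates all failed (`NULL`, empty, or all-`NA`) are
#'   dropped with a warning; at least 3 points must survive.
#' @param config An [assay_config()].
#' @return An object of class `mix_fit` with fields `expected_fractions`,
#'   `observed_fractions`, `slope`, `intercept`, `r_squared`, `n_points` and
#'   the underlying `lm` fit.
#' @export
mixing_series_fit <- function(expected, measured, config = assay_config()) {
  expected <- as.numeric(expected)
  if (any(!is.finite(expected)) || any(expected <= 0 | expected >= 1))
    stop("expected fractions must lie strictly in (0, 1)")
  if (length(expected) < 3L)
    stop("need at least 3 mixture points, got ", length(expected))
  if (!is.list(measured) || length(measured) != length(expected))
    stop("measured must be a list with one element per expected point")

  point_ratios <- lapply(measured, function(m) {
    r <- if (is.data.frame(m)) m$ratio else as.numeric(m)
    r[is.finite(r) & r > 0]
  })
  keep <- vapply(point_ratios, length, integer(1)) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " mixture point(s) dropped: all replicates failed")
    if (sum(keep) < 3L)
      stop("fewer than 3 mixture points survive after dropping failed points")
  }
  expected <- expected[keep]
  point_ratios <- point_ratios[keep]

  if (config$fraction_regression) {
    x <- expected
    y <- vapply(point_ratios, function(r) mean(r / (1 + r)), numeric(1))
  } else {
    x <- expected / (1 - expected)
    y <- vapply(point_ratios, mean, numeric(1))
  }
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(
    list(expected_fractions = expected,
         observed_fractions = if (config$fraction_regression) y
                              else vapply(point_ratios,
                                          function(r) mean(r / (1 + r)), numeric(1)),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2,
         n_points = length(expected),
         n_replicates = vapply(point_ratios, length, integer(1)),
         fraction_regression = config$fraction_regression,
         lm = fit),
    class = "mix_fit"
  )
}

#' @export
print.mix_fit <- function(x, ...) {
  cat(sprintf("<mix_fit> %d mixture points (%s regression)\n", x$n_points,
              if (x$fraction_regression) "fraction" else "raw-ratio"))
  cat(sprintf("  observed = %.4f + %.4f * expected,  R^2 = %.4f\n",
              x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' @export
summary.mix_fit <- function(object, ...) {
  print(object)
  print(data.frame(expected = object$expected_fractions,
                   observed = round(object$observed_fractions, 4),
                   n = object$n_replicates))
  invisible(object)
}

#' @export
coef.mix_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.mix_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$expected_fractions else as.numeric(newdata)
  if (!object$fraction_regression) x <- x / (1 - x)
  object$intercept + object$slope * x
}

#' @export
plot.mix_fit <- function(x, ...,
                         xlab = "Expected allele-2 fraction",
                         ylab = "Observed allele-2 fraction",
                         main = sprintf("Mixing series (R² = %.3f)", x$r_squared)) {
  graphics::plot(x$expected_fractions, x$observed_fractions,
                 xlab = xlab, ylab = ylab, main = main, pch = 19, ...)
  graphics::abline(a = x$intercept, b = x$slope)
  graphics::abline(a = 0, b = 1, lty = 3, col = "grey")
  invisible(x)
}
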