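# From raw fluorescence to the smoothed negative-derivative melting curve.
# The no-template control is the local-background baseline; smoothing and
# differentiation happen in a single Savitzky-Golay pass.

#' Pointwise mean of several NTC curves
#'
#' When a batch carries more than one no-template control, the baseline is
#' their pointwise mean (curves on differing grids are linearly interpolated
#' onto the first NTC's grid).
#'
#' @param ntcs List of NTC [melt_curve()] objects.
#' @return A single NTC `melt_curve`.
#' @export
average_ntc <- function(ntcs) {
  if (!length(ntcs)) stop("no NTC curves supplied")
  for (cu in ntcs)
    if (cu$material != "NTC") stop("average_ntc() expects NTC wells only")
  if (length(ntcs) == 1L) return(ntcs[[1]])
  ref <- ntcs[[1]]
  mat <- vapply(ntcs, function(cu) {
    if (isTRUE(all.equal(cu$temperatures, ref$temperatures))) cu$fluorescence
    else stats::approx(cu$temperatures, cu$fluorescence,
                       xout = ref$temperatures, rule = 2)$y
  }, numeric(length(ref$temperatures)))
  melt_curve(well_id = paste0("NTC_mean_", length(ntcs)),
             sample_id = "NTC", material = "NTC", replicate = 1L,
             marker_snp = ref$marker_snp,
             temperatures = ref$temperatures, fluorescence = rowMeans(mat))
}

#' Subtract the no-template-control baseline
#'
#' Subtracts the NTC fluorescence, evaluated at the sample curve's
#' temperatures (linear interpolation when the grids differ), from the sample
#' fluorescence. The NTC must cover at least 90% of the sample's temperature
#' range.
#'
#' @param curve Sample [melt_curve()].
#' @param ntc An NTC [melt_curve()] (material must be `NTC`).
#' @return The background-subtracted `melt_curve` (metadata preserved,
#'   `background_subtracted` flag set).
#' @export
subtract_background <- function(curve, ntc) {
  if (ntc$material != "NTC")
    stop("background curve must have material NTC, got ", ntc$material)
  r_s <- range(curve$temperatures)
  r_n <- range(ntc$temperatures)
  covered <- max(0, min(r_s[2], r_n[2]) - max(r_s[1], r_n[1]))
  if (covered < 0.9 * (r_s[2] - r_s[1]))
    stop(sprintf("NTC covers only %.0f%% of the sample temperature range (need >= 90%%)",
                 100 * covered / (r_s[2] - r_s[1])))
  bg <- if (isTRUE(all.equal(ntc$temperatures, curve$temperatures))) {
    ntc$fluorescence
  } else {
    stats::approx(ntc$temperatures, ntc$fluorescence,
                  xout = curve$temperatures, rule = 2)$y
  }
  out <- curve
  out$fluorescence <- curve$fluorescence - bg
  out$background_subtracted <- TRUE
  out
}

#' Savitzky-Golay smoothing / differentiation
#'
#' Least-squares local polynomial filtering: `deriv = 0` returns the smoothed
#' series, `deriv = 1` the first derivative with respect to the sampling
#' variable, scaled by `step`. Near the edges the polynomial is fitted on the
#' full first (last) window and evaluated off-centre, so polynomials up to
#' degree `order` are reproduced exactly everywhere.
#'
#' @param values Numeric series, `length(values) >= window`.
#' @param window Odd window length in points.
#' @param order Polynomial order, `< window`.
#' @param deriv 0 (smooth) or 1 (first derivative).
#' @param step Grid spacing used to scale the derivative (default 1).
#' @return Numeric vector, same length as `values`.
#' @export
savitzky_golay <- function(values, window, order, deriv = 0L, step = 1) {
  window <- as.integer(window)
  order <- as.integer(order)
  if (window %% 2L == 0L) stop("window must be odd")
  if (order >= window) stop("order must be smaller than window")
  if (!deriv %in% c(0L, 1L)) stop("deriv must be 0 or 1")
  if (length(values) < window)
    stop(sprintf("series of length %d is shorter than the window (%d points)",
                 length(values), window))
  if (step <= 0) stop("step must be positive")
  as.numeric(signal::sgolayfilt(values, p = order, n = window,
                                m = deriv, ts = step))
}

#' Smoothed negative-derivative melting curve
#'
#' Computes `-dF/dT` in one combined Savitzky-Golay smoothing and
#' differentiation pass, using the filter settings in `config`. Melting
#' transitions appear as positive peaks at the allele Tm values.
#'
#' @param curve A (background-subtracted) [melt_curve()]. Curves that still
#'   carry their baseline are accepted but the result keeps the
#'   `background_subtracted = FALSE` flag.
#' @param config An [assay_config()].
#' @return An object of class `derivative_curve` with fields
#'   `temperatures` and `neg_dfdt` plus the sample metadata.
#' @export
derivative_curve <- function(curve, config = assay_config()) {
  if (length(curve$temperatures) < config$sg_window)
    stop(sprintf("curve has %d points, shorter than sg_window = %d",
                 length(curve$temperatures), config$sg_window))
  nd <- -savitzky_golay(curve$fluorescence, config$sg_window, config$sg_order,
                        deriv = 1L, step = grid_step(curve))
  if (!all(is.finite(nd))) stop("non-finite values in derivative curve")
  structure(
    list(well_id = curve$well_id, sample_id = curve$sample_id,
         material = curve$material, replicate = curve$replicate,
         marker_snp = curve$marker_snp,
         temperatures = curve$temperatures, neg_dfdt = nd,
         background_subtracted = curve$background_subtracted),
    class = "derivative_curve"
  )
}

#' @export
print.derivative_curve <- function(x, ...) {
  cat(sprintf("<derivative_curve> well %s | %s %s rep %d | peak -dF/dT %.3g at %.1f degC\n",
              x$well_id, x$sample_id, x$material, x$replicate,
              max(x$neg_dfdt), x$temperatures[which.max(x$neg_dfdt)]))
  invisible(x)
}

#' @export
plot.derivative_curve <- function(x, ...,
                                  xlab = "Temperature (°C)",
                                  ylab = "-dF/dT (a.u./°C)",
                                  type = "l",
                                  main = sprintf("%s (%s, rep %d)", x$sample_id,
                                                 x$material, x$replicate)) {
  graphics::plot(x$temperatures, x$neg_dfdt, type = type,
                 xlab = xlab, ylab = ylab, main = main, ...)
  invisible(x)
}
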