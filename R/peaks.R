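# Locating the two allele-specific peaks on the derivative plot and turning
# their heights into the per-replicate allelic ratio h2/h1 (Allele 2 is the
# higher-Tm allele by convention; the DAE statistics use |delta|, so the
# orientation cannot flip a call).

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1L)] > v[1:(n - 2L)] & v[2:(n - 1L)] > v[3:n]) + 1L
}

find_window_peak <- function(d, window, label, floor, parabolic) {
  idx <- which(d$temperatures >= window[1] & d$temperatures <= window[2])
  if (length(idx) < 3L) stop_peak_not_found(label, window)
  v <- d$neg_dfdt[idx]
  cand <- local_maxima(v)
  if (!length(cand)) stop_peak_not_found(label, window)
  best <- cand[v[cand] == max(v[cand])]
  if (length(best) > 1L) {
    centre <- (window[1] + window[2]) / 2
    best <- best[which.min(abs(d$temperatures[idx][best] - centre))]
  }
  h <- v[best]
  tm <- d$temperatures[idx][best]
  if (parabolic) {
    i <- idx[best]
    if (i > 1L && i < length(d$neg_dfdt)) {
      y0 <- d$neg_dfdt[i - 1L]; y1 <- d$neg_dfdt[i]; y2 <- d$neg_dfdt[i + 1L]
      den <- y0 - 2 * y1 + y2
      if (den < 0) {                       # concave: refine vertex
        off <- 0.5 * (y0 - y2) / den
        if (abs(off) <= 1) {
          h <- y1 - 0.25 * (y0 - y2) * off
          tm <- tm + off * (d$temperatures[i + 1L] - d$temperatures[i])
        }
      }
    }
  }
  if (h <= floor) stop_low_signal(label, h, floor)
  list(tm = tm, h = h)
}

#' Detect the two allele peaks
#'
#' Within each configured allele Tm window, picks the highest local maximum of
#' `neg_dfdt` (a point strictly greater than both neighbours; ties broken
#' toward the window centre). The peak height is the smoothed `neg_dfdt` value
#' at that point. Peaks at or below the noise floor — `noise_floor_mad` times
#' the median absolute deviation of `neg_dfdt` outside both windows — raise a
#' `melt_low_signal` condition; windows with no local maximum raise
#' `melt_peak_not_found` (failed PCR or a homozygous sample).
#'
#' @param d A [derivative_curve()].
#' @param config An [assay_config()] with windows for `d$marker_snp`.
#' @return An object of class `peak_pair`: `tm1`, `h1`, `tm2`, `h2` plus
#'   allele labels.
#' @export
detect_peaks <- function(d, config) {
  m <- marker_windows(config, d$marker_snp)
  outside <- d$neg_dfdt[!(
    (d$temperatures >= m$allele1_window[1] & d$temperatures <= m$allele1_window[2]) |
    (d$temperatures >= m$allele2_window[1] & d$temperatures <= m$allele2_window[2]))]
  floor <- if (length(outside) >= 5L)
    config$noise_floor_mad * stats::mad(outside) else 0
  p1 <- find_window_peak(d, m$allele1_window, "allele1", floor,
                         config$parabolic_refinement)
  p2 <- find_window_peak(d, m$allele2_window, "allele2", floor,
                         config$parabolic_refinement)
  structure(
    list(tm1 = p1$tm, h1 = p1$h, tm2 = p2$tm, h2 = p2$h,
         allele1_label = m$allele1_label, allele2_label = m$allele2_label,
         marker_snp = d$marker_snp),
    class = "peak_pair"
  )
}

#' @export
print.peak_pair <- function(x, ...) {
  cat(sprintf("<peak_pair> %s: %s Tm %.2f degC h %.4g | %s Tm %.2f degC h %.4g | h2/h1 = %.4g\n",
              x$marker_snp, x$allele1_label, x$tm1, x$h1,
              x$allele2_label, x$tm2, x$h2, x$h2 / x$h1))
  invisible(x)
}

#' Allelic ratio of a peak pair
#'
#' The Allele 2 / Allele 1 ratio is the ratio of the two derivative peak
#' heights, `h2/h1`; its natural log is the per-replicate measurement
#' aggregated by [dae_estimate()].
#'
#' @param p A `peak_pair` from [detect_peaks()].
#' @param sample_id,material,replicate Optional annotation carried along.
#' @return A one-row data.frame of class `ratio_measurement` with columns
#'   `sample_id`, `material`, `replicate`, `ratio`, `log_ratio`.
#' @export
allelic_ratio <- function(p, sample_id = NA_character_, material = NA_character_,
                          replicate = NA_integer_) {
  if (!inherits(p, "peak_pair")) stop("allelic_ratio() expects a peak_pair")
  if (!(p$h1 > 0 && p$h2 > 0)) stop("peak heights must be positive")
  if (!(p$tm1 < p$tm2)) stop("invalid peak pair: tm1 must be below tm2")
  ratio <- p$h2 / p$h1
  out <- data.frame(sample_id = as.character(sample_id),
                    material = as.character(material),
                    replicate = as.integer(replicate),
                    ratio = ratio, log_ratio = log(ratio),
                    stringsAsFactors = FALSE)
  class(out) <- c("ratio_measurement", "data.frame")
  out
}
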