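#' Assay configuration
#'
#' Bundles the per-marker allele Tm windows with the analysis constants: the
#' Savitzky-Golay filter settings used for the derivative melting curve, the
#' DAE calling thresholds, and a few behavioural switches.
#'
#' @param markers Named list, one entry per marker SNP. Each entry is a list
#'   with `allele1_window` and `allele2_window` (numeric `c(low, high)` in
#'   degC, allele 1 being the lower-Tm allele) and optional `allele1_label`,
#'   `allele2_label` character labels.
#' @param sg_window Savitzky-Golay window length in points (odd integer).
#'   The default, 17 points (1.6 degC on a 0.1 degC grid), resolves probe
#'   melting transitions of ~3.5 degC full width while keeping the
#'   derivative-noise contribution to peak heights small.
#' @param sg_order Polynomial order of the filter; must be `< sg_window`.
#' @param dae_threshold_percent Magnitude criterion: DAE is only called when
#'   `dae_percent` exceeds this value (default 20).
#' @param alpha Significance level for the t-test criterion (default 0.05).
#' @param ci_level Confidence level for the interval on the log-ratio
#'   difference (default 0.95).
#' @param var_equal If `TRUE` use the pooled-variance Student t-test;
#'   the default `FALSE` uses the Welch t-test (the default of R's
#'   [stats::t.test()]), which keeps confidence-interval coverage close to
#'   nominal when cDNA replicate ratios scatter more than genomic-DNA ones.
#' @param noise_floor_mad Peak heights at or below `noise_floor_mad` times the
#'   median absolute deviation of the derivative signal outside both allele
#'   windows raise a low-signal condition (default 3).
#' @param parabolic_refinement If `TRUE`, refine each peak height/Tm by a
#'   3-point parabola through the grid maximum (off by default: heights are
#'   read directly from the smoothed derivative).
#' @param bh_correction If `TRUE`, [analyze_batch()] applies a
#'   Benjamini-Hochberg correction across individuals before the p-value
#'   criterion (off by default: calling is per-sample).
#' @param fraction_regression If `TRUE` (default) [mixing_series_fit()]
#'   regresses observed allele-2 fractions `h2/(h1+h2)` on the expected
#'   fractions; if `FALSE` it regresses raw ratios `h2/h1` on expected ratios.
#' @return An object of class `assay_config`.
#' @examples
#' cfg <- assay_config(markers = list(
#'   rs0001 = list(allele1_window = c(50, 57), allele2_window = c(57.5, 64))
#' ))
#' cfg
#' @export
assay_config <- function(markers = list(),
                         sg_window = 17L,
                         sg_order = 3L,
                         dae_threshold_percent = 20,
                         alpha = 0.05,
                         ci_level = 0.95,
                         var_equal = FALSE,
                         noise_floor_mad = 3,
                         parabolic_refinement = FALSE,
                         bh_correction = FALSE,
                         fraction_regression = TRUE) {
  sg_window <- as.integer(sg_window)
  sg_order <- as.integer(sg_order)
  if (sg_window %% 2L == 0L) stop("sg_window must be odd")
  if (sg_order >= sg_window) stop("sg_order must be smaller than sg_window")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  if (dae_threshold_percent < 0 || dae_threshold_percent >= 100)
    stop("dae_threshold_percent must be in [0, 100)")

  markers <- lapply(markers, function(m) {
    w1 <- as.numeric(m$allele1_window)
    w2 <- as.numeric(m$allele2_window)
    if (length(w1) != 2L || length(w2) != 2L || w1[1] >= w1[2] || w2[1] >= w2[2])
      stop("each allele window must be c(low, high) with low < high")
    if (w1[2] >= w2[1])
      stop("allele1_window must lie entirely below allele2_window")
    list(allele1_window = w1, allele2_window = w2,
         allele1_label = if (is.null(m$allele1_label)) "allele1" else m$allele1_label,
         allele2_label = if (is.null(m$allele2_label)) "allele2" else m$allele2_label)
  })

  structure(
    list(markers = markers, sg_window = sg_window, sg_order = sg_order,
         dae_threshold_percent = dae_threshold_percent, alpha = alpha,
         ci_level = ci_level, var_equal = var_equal,
         noise_floor_mad = noise_floor_mad,
         parabolic_refinement = parabolic_refinement,
         bh_correction = bh_correction,
         fraction_regression = fraction_regression),
    class = "assay_config"
  )
}

#' @export
print.assay_config <- function(x, ...) {
  cat("<assay_config>\n")
  cat(sprintf("  markers: %s\n",
              if (length(x$markers)) paste(names(x$markers), collapse = ", ") else "(none)"))
  for (nm in names(x$markers)) {
    m <- x$markers[[nm]]
    cat(sprintf("    %s: allele1 [%.1f, %.1f] | allele2 [%.1f, %.1f] degC\n",
                nm, m$allele1_window[1], m$allele1_window[2],
                m$allele2_window[1], m$allele2_window[2]))
  }
  cat(sprintf("  Savitzky-Golay: window %d, order %d\n", x$sg_window, x$sg_order))
  cat(sprintf("  DAE criteria: > %g%%, p <= %g, %g%% CI excluding 0 (%s t)\n",
              x$dae_threshold_percent, x$alpha, 100 * x$ci_level,
              if (x$var_equal) "pooled" else "Welch"))
  invisible(x)
}

#' Read an assay configuration from YAML or JSON
#'
#' The file mirrors the arguments of [assay_config()]: a `markers` mapping plus
#' any of the scalar settings. Format is chosen by file extension
#' (`.yml`/`.yaml` vs `.json`).
#'
#' @param path Path to the configuration file.
#' @return An [assay_config()] object.
#' @export
read_assay_config <- function(path) {
  if (!file.exists(path)) stop("assay config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported assay config format: .", ext, " (use YAML or JSON)")
  }
  markers <- raw$markers
  if (is.null(markers)) markers <- list()
  raw$markers <- NULL
  known <- names(formals(assay_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    warning("ignoring unknown assay config fields: ", paste(unknown, collapse = ", "))
  do.call(assay_config, c(list(markers = markers), raw[intersect(names(raw), known)]))
}

marker_windows <- function(config, marker_snp) {
  m <- config$markers[[marker_snp]]
  if (is.null(m))
    stop("no allele windows configured for marker SNP '", marker_snp, "'")
  m
}
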