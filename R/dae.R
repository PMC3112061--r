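# The DAE estimator: replicate log allelic ratios of cDNA are normalized
# against the genomic-DNA log ratios (the 1:1 internal control that cancels
# probe fluorescence-yield bias), tested with a two-sample t-test, and called
# by the three-criteria rule. Puromycin-treated cDNA (NMD inhibition) is used
# to classify positive calls.

# Accept either a ratio_measurement data.frame (log_ratio column) or a bare
# numeric vector of ratios.
extract_log_ratios <- function(x, what) {
  if (is.data.frame(x)) {
    if (!"log_ratio" %in% names(x))
      stop(what, " data.frame must have a log_ratio column")
    lr <- x$log_ratio
  } else if (is.numeric(x)) {
    if (any(x <= 0)) stop(what, " ratios must be positive")
    lr <- log(x)
  } else {
    stop(what, " must be a ratio_measurement data.frame or a numeric vector of ratios")
  }
  lr <- lr[is.finite(lr)]
  if (length(lr) < 2L)
    stop("need at least 2 usable ", what, " replicates, got ", length(lr))
  lr
}

#' Estimate differential allelic expression for one individual
#'
#' The DAE point estimate is `delta`, the difference between the mean of the
#' replicate log allelic ratios in cDNA and the corresponding mean in genomic
#' DNA. `dae_percent = 100 * (1 - exp(-|delta|))` expresses it as the percent
#' reduction of the lower-expressed allele relative to the other; a 50%
#' allele-specific degradation gives `dae_percent = 50`. Significance comes
#' from a two-sample t-test on the two groups of replicate log ratios (Welch
#' by default, pooled Student when `config$var_equal`), with a confidence
#' interval on `delta` at `config$ci_level`.
#'
#' If both groups have zero variance the test degenerates: `p = 0` when
#' `delta != 0`, `p = 1` when `delta == 0`, with the `degenerate_variance`
#' flag set and a point confidence interval.
#'
#' @param gdna,cdna Replicate measurements for one individual and one marker
#'   SNP: a `ratio_measurement` data.frame from [allelic_ratio()] or a bare
#'   numeric vector of `h2/h1` ratios. At least 2 replicates each.
#' @param config An [assay_config()].
#' @param sample_id,marker_snp Optional identifiers (taken from the data if
#'   present there).
#' @return An object of class `dae_result` (criteria flags unset until
#'   [call_dae()]).
#' @examples
#' res <- dae_estimate(gdna = c(0.80, 0.82, 0.78, 0.80),
#'                     cdna = c(0.40, 0.41, 0.39, 0.40))
#' call_dae(res)
#' @export
dae_estimate <- function(gdna, cdna, config = assay_config(),
                         sample_id = NULL, marker_snp = NA_character_) {
  if (is.null(sample_id)) {
    sample_id <- if (is.data.frame(cdna) && "sample_id" %in% names(cdna))
      cdna$sample_id[1] else NA_character_
  }
  if (is.data.frame(cdna) && "sample_id" %in% names(cdna)) {
    ids <- unique(stats::na.omit(c(
      if (is.data.frame(gdna)) gdna$sample_id else NULL, cdna$sample_id)))
    if (length(ids) > 1L)
      stop("replicates from more than one sample_id: ", paste(ids, collapse = ", "))
  }
  lg <- extract_log_ratios(gdna, "gDNA")
  lc <- extract_log_ratios(cdna, "cDNA")
  delta <- mean(lc) - mean(lg)
  degenerate <- stats::sd(lg) < 1e-12 && stats::sd(lc) < 1e-12
  if (degenerate) {
    tt <- list(statistic = if (delta == 0) 0 else sign(delta) * Inf,
               parameter = length(lg) + length(lc) - 2,
               p.value = if (delta == 0) 1 else 0,
               conf.int = c(delta, delta))
  } else {
    tt <- stats::t.test(lc, lg, var.equal = config$var_equal,
                        conf.level = config$ci_level)
  }
  structure(
    list(sample_id = as.character(sample_id), marker_snp = as.character(marker_snp),
         n_gdna = length(lg), n_cdna = length(lc), n_puro = NA_integer_,
         mean_log_gdna = mean(lg), mean_log_cdna = mean(lc),
         mean_log_puro = NA_real_,
         delta = delta, dae_percent = 100 * (1 - exp(-abs(delta))),
         ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
         t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, p_used = tt$p.value,
         crit_magnitude = NA, crit_pvalue = NA, crit_ci = NA, call = NA,
         nmd_class = NA_character_, puromycin = NULL,
         degenerate_variance = degenerate, no_background = FALSE,
         status = "ok", failure_reason = NA_character_,
         ci_level = config$ci_level),
    class = "dae_result"
  )
}

#' Apply the three DAE criteria
#'
#' DAE is called when all of: (i) the point estimate exceeds the magnitude
#' threshold (`dae_percent > config$dae_threshold_percent`), (ii) the t-test
#' p-value is at most `config$alpha`, and (iii) the confidence interval on
#' `delta` does not include 0.
#'
#' @param result A `dae_result` from [dae_estimate()].
#' @param config An [assay_config()].
#' @return The `dae_result` with `crit_magnitude`, `crit_pvalue`, `crit_ci`
#'   and `call` filled in.
#' @export
call_dae <- function(result, config = assay_config()) {
  stopifnot(inherits(result, "dae_result"))
  result$crit_magnitude <- result$dae_percent > config$dae_threshold_percent
  result$crit_pvalue <- result$p_used <= config$alpha
  result$crit_ci <- (result$ci_low > 0) || (result$ci_high < 0)
  result$call <- result$crit_magnitude && result$crit_pvalue && result$crit_ci
  result
}

#' Classify a DAE call with the puromycin rescue experiment
#'
#' Puromycin inhibits nonsense-mediated mRNA decay (NMD). The DAE estimate is
#' recomputed with puromycin-treated cDNA in place of untreated cDNA:
#' \describe{
#'   \item{no_dae}{the untreated call is negative;}
#'   \item{nmd_consistent}{untreated call positive, and the puromycin profile
#'     resembles genomic DNA (`dae_percent` at or below the magnitude
#'     threshold and a confidence interval including 0);}
#'   \item{regulatory_consistent}{untreated call positive and the puromycin
#'     estimate still meets all three criteria (imbalance not rescued);}
#'   \item{indeterminate}{anything else, including missing puromycin data
#'     (with a warning).}
#' }
#'
#' @param result A called `dae_result` for untreated cDNA (see [call_dae()]).
#' @param puro Replicate measurements for puromycin-treated cDNA (same form
#'   as in [dae_estimate()]), or `NULL` if unavailable.
#' @param gdna The genomic-DNA replicate measurements (internal control).
#' @param config An [assay_config()].
#' @return The `dae_result` with `nmd_class`, puromycin summary fields and
#'   the puromycin sub-estimate in `$puromycin`.
#' @export
nmd_assessment <- function(result, puro, gdna, config = assay_config()) {
  stopifnot(inherits(result, "dae_result"))
  if (is.na(result$call))
    stop("run call_dae() before nmd_assessment()")
  n_puro <- if (is.null(puro)) 0L else if (is.data.frame(puro)) nrow(puro) else length(puro)
  if (n_puro < 2L) {
    warning("no (or insufficient) puromycin replicates for ", result$sample_id,
            ": NMD class is indeterminate")
    result$nmd_class <- "indeterminate"
    return(result)
  }
  pe <- dae_estimate(gdna, puro, config,
                     sample_id = result$sample_id, marker_snp = result$marker_snp)
  pe <- call_dae(pe, config)
  result$n_puro <- pe$n_cdna
  result$mean_log_puro <- pe$mean_log_cdna
  result$puromycin <- pe
  ci_includes_zero <- pe$ci_low <= 0 && pe$ci_high >= 0
  result$nmd_class <-
    if (!result$call) "no_dae"
    else if (pe$dae_percent <= config$dae_threshold_percent && ci_includes_zero)
      "nmd_consistent"
    else if (pe$call) "regulatory_consistent"
    else "indeterminate"
  result
}

#' One-call DAE analysis for a single individual
#'
#' Convenience wrapper chaining [dae_estimate()], [call_dae()] and (when
#' puromycin data are given) [nmd_assessment()].
#'
#' @inheritParams dae_estimate
#' @param puromycin Optional puromycin-treated cDNA replicates.
#' @return A `dae_result`.
#' @examples
#' dae_test(gdna = c(0.80, 0.82, 0.78, 0.80),
#'          cdna = c(0.40, 0.41, 0.39, 0.40),
#'          puromycin = c(0.78, 0.80, 0.81, 0.79))
#' @export
dae_test <- function(gdna, cdna, puromycin = NULL, config = assay_config(),
                     sample_id = NULL, marker_snp = NA_character_) {
  res <- dae_estimate(gdna, cdna, config, sample_id = sample_id,
                      marker_snp = marker_snp)
  res <- call_dae(res, config)
  if (!is.null(puromycin)) res <- nmd_assessment(res, puromycin, gdna, config)
  res
}

#' @export
print.dae_result <- function(x, digits = 4, ...) {
  cat(sprintf("<dae_result> %s%s\n", x$sample_id,
              if (!is.na(x$marker_snp)) paste0(" (", x$marker_snp, ")") else ""))
  if (x$status != "ok") {
    cat("  status:", x$status,
        if (!is.na(x$failure_reason)) paste0(" (", x$failure_reason, ")") else "", "\n")
    return(invisible(x))
  }
  cat(sprintf("  mean log ratio: gDNA %.*f (n=%d) | cDNA %.*f (n=%d)%s\n",
              digits, x$mean_log_gdna, x$n_gdna, digits, x$mean_log_cdna, x$n_cdna,
              if (!is.na(x$mean_log_puro))
                sprintf(" | puromycin %.*f (n=%d)", digits, x$mean_log_puro, x$n_puro)
              else ""))
  cat(sprintf("  delta = %.*f  DAE = %.1f%%  %g%% CI [%.*f, %.*f]\n",
              digits, x$delta, x$dae_percent, 100 * x$ci_level,
              digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  t = %.3f (df %.2f), p = %.3g%s\n", x$t_stat, x$df, x$p_value,
              if (x$degenerate_variance) " [degenerate variance]" else ""))
  if (!is.na(x$call))
    cat(sprintf("  criteria: magnitude %s | p-value %s | CI %s  ->  call: %s%s\n",
                x$crit_magnitude, x$crit_pvalue, x$crit_ci,
                if (x$call) "DAE" else "no DAE",
                if (!is.na(x$nmd_class)) paste0(" (", x$nmd_class, ")") else ""))
  invisible(x)
}

#' @export
summary.dae_result <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$puromycin)) {
    cat("  puromycin estimate:\n")
    cat(sprintf("    delta = %.4f  DAE = %.1f%%  CI [%.4f, %.4f], p = %.3g\n",
                object$puromycin$delta, object$puromycin$dae_percent,
                object$puromycin$ci_low, object$puromycin$ci_high,
                object$puromycin$p_value))
  }
  invisible(object)
}

#' @export
coef.dae_result <- function(object, ...) c(delta = object$delta)

#' @export
confint.dae_result <- function(object, parm = "delta", level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$ci_level)))
    stop("interval was computed at level ", object$ci_level,
         "; re-run dae_estimate() with ci_level = ", level)
  m <- matrix(c(object$ci_low, object$ci_high), nrow = 1,
              dimnames = list("delta",
                              sprintf("%g %%", 100 * c((1 - object$ci_level) / 2,
                                                       1 - (1 - object$ci_level) / 2))))
  m
}

#' @export
as.data.frame.dae_result <- function(x, ...) {
  data.frame(
    sample_id = x$sample_id, marker_snp = x$marker_snp, status = x$status,
    n_gdna = x$n_gdna, n_cdna = x$n_cdna, n_puro = x$n_puro,
    mean_log_gdna = x$mean_log_gdna, mean_log_cdna = x$mean_log_cdna,
    mean_log_puro = x$mean_log_puro,
    delta = x$delta, dae_percent = x$dae_percent,
    ci_low = x$ci_low, ci_high = x$ci_high,
    t_stat = x$t_stat, p_value = x$p_value,
    crit_magnitude = x$crit_magnitude, crit_pvalue = x$crit_pvalue,
    crit_ci = x$crit_ci, call = x$call,
    nmd_class = if (is.na(x$nmd_class)) NA_character_ else x$nmd_class,
    stringsAsFactors = FALSE)
}
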