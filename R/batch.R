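# Orchestration of the full pipeline for one plate batch: background
# subtraction against the batch NTC mean, derivative curves, peak detection,
# per-replicate ratios, then per-individual estimate -> call -> NMD class.
# Failed wells are excluded with QC log entries, never silently.

failed_dae_result <- function(sample_id, marker_snp, reason) {
  structure(
    list(sample_id = sample_id, marker_snp = marker_snp,
         n_gdna = NA_integer_, n_cdna = NA_integer_, n_puro = NA_integer_,
         mean_log_gdna = NA_real_, mean_log_cdna = NA_real_,
         mean_log_puro = NA_real_,
         delta = NA_real_, dae_percent = NA_real_,
         ci_low = NA_real_, ci_high = NA_real_,
         t_stat = NA_real_, df = NA_real_, p_value = NA_real_, p_used = NA_real_,
         crit_magnitude = NA, crit_pvalue = NA, crit_ci = NA, call = NA,
         nmd_class = NA_character_, puromycin = NULL,
         degenerate_variance = FALSE, no_background = FALSE,
         status = "failed_qc", failure_reason = reason, ci_level = NA_real_),
    class = "dae_result"
  )
}

harmonize_grids <- function(curves, log_fn) {
  ref <- curves[[1]]$temperatures
  lapply(curves, function(cu) {
    if (isTRUE(all.equal(cu$temperatures, ref))) return(cu)
    log_fn(sprintf("well %s: temperature grid differs; linearly interpolated onto the batch grid",
                   cu$well_id))
    cu$fluorescence <- stats::approx(cu$temperatures, cu$fluorescence,
                                     xout = ref, rule = 2)$y
    cu$temperatures <- ref
    cu
  })
}

#' Analyze one plate batch end to end
#'
#' Runs the whole pipeline for every individual on the plate: all sample
#' wells are background-subtracted against the pointwise mean of the batch's
#' NTC wells, converted to smoothed negative-derivative curves, and their two
#' allele peaks quantified into per-replicate `h2/h1` ratios. Per individual,
#' the cDNA log ratios are then normalized against the genomic-DNA log ratios
#' ([dae_estimate()]), the three criteria applied ([call_dae()]) and the
#' puromycin replicates used for NMD classification ([nmd_assessment()]).
#'
#' Wells whose peaks cannot be quantified (`melt_peak_not_found`,
#' `melt_low_signal`) are excluded with a QC log entry; individuals left with
#' fewer than 2 usable replicates of gDNA or cDNA are reported with status
#' `failed_qc`, not dropped. Without any NTC well the batch is analyzed
#' unsubtracted and every result carries the `no_background` flag.
#'
#' @param curves List of [melt_curve()] objects covering the layout's wells
#'   (e.g. from [read_melt_table()]).
#' @param layout The batch's [plate_layout()].
#' @param config An [assay_config()] with windows for the plate's marker SNPs.
#' @return An object of class `dae_batch`: the per-individual `dae_result`s
#'   plus the QC log. `as.data.frame()` yields the results table written by
#'   [write_results_table()].
#' @export
analyze_batch <- function(curves, layout, config = assay_config()) {
  qc <- character(0)
  log_qc <- function(msg) qc[[length(qc) + 1L]] <<- msg

  have <- vapply(curves, function(cu) cu$well_id, character(1))
  missing_wells <- setdiff(layout$well, have)
  if (length(missing_wells))
    log_qc(paste("wells in layout without curves:",
                 paste(missing_wells, collapse = ", ")))

  curves <- harmonize_grids(curves, log_qc)
  is_ntc <- vapply(curves, function(cu) cu$material == "NTC", logical(1))
  no_background <- !any(is_ntc)
  if (no_background) {
    log_qc("no NTC well in batch: proceeding without background subtraction")
    ntc <- NULL
  } else {
    ntc <- average_ntc(curves[is_ntc])
  }

  # Per-well quantification.
  rows <- list()
  for (cu in curves[!is_ntc]) {
    res <- tryCatch({
      work <- if (is.null(ntc)) cu else subtract_background(cu, ntc)
      d <- derivative_curve(work, config)
      allelic_ratio(detect_peaks(d, config),
                    sample_id = cu$sample_id, material = cu$material,
                    replicate = cu$replicate)
    }, melt_error = function(e) {
      log_qc(sprintf("well %s (%s %s rep %d): %s", cu$well_id, cu$sample_id,
                     cu$material, cu$replicate, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  meas <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), material = character(),
               replicate = integer(), ratio = numeric(), log_ratio = numeric())

  sample_ids <- unique(layout$sample_id[layout$material != "NTC"])
  markers <- vapply(sample_ids, function(s)
    layout$marker_snp[layout$sample_id == s][1], character(1))

  results <- vector("list", length(sample_ids))
  names(results) <- sample_ids
  for (i in seq_along(sample_ids)) {
    s <- sample_ids[[i]]
    g <- meas[meas$sample_id == s & meas$material == "gDNA", , drop = FALSE]
    cc <- meas[meas$sample_id == s & meas$material == "cDNA", , drop = FALSE]
    pp <- meas[meas$sample_id == s & meas$material == "cDNA_puromycin", , drop = FALSE]
    if (nrow(g) < 2L || nrow(cc) < 2L) {
      reason <- sprintf("<2 usable replicates (gDNA %d, cDNA %d)", nrow(g), nrow(cc))
      log_qc(sprintf("individual %s failed QC: %s", s, reason))
      results[[i]] <- failed_dae_result(s, markers[[i]], reason)
      next
    }
    r <- dae_estimate(g, cc, config, sample_id = s, marker_snp = markers[[i]])
    r$no_background <- no_background
    r$puro_data <- pp           # stashed until calling, for NMD step below
    results[[i]] <- r
  }

  ok <- vapply(results, function(r) r$status == "ok", logical(1))
  if (config$bh_correction && any(ok)) {
    padj <- stats::p.adjust(vapply(results[ok], `[[`, numeric(1), "p_value"),
                            method = "BH")
    results[ok] <- Map(function(r, p) { r$p_used <- p; r }, results[ok], padj)
    log_qc("Benjamini-Hochberg correction applied across individuals")
  }
  for (i in which(ok)) {
    r <- call_dae(results[[i]], config)
    pp <- r$puro_data
    r$puro_data <- NULL
    r <- withCallingHandlers(
      nmd_assessment(r, if (nrow(pp) >= 2L) pp else NULL,
                     meas[meas$sample_id == r$sample_id &
                            meas$material == "gDNA", , drop = FALSE],
                     config),
      warning = function(w) {
        log_qc(conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    results[[i]] <- r
  }

  structure(list(results = results, qc_log = qc,
                 no_background = no_background),
            class = "dae_batch")
}

#' @export
print.dae_batch <- function(x, ...) {
  df <- as.data.frame(x)
  calls <- sum(df$call, na.rm = TRUE)
  failed <- sum(df$status != "ok")
  cat(sprintf("<dae_batch> %d individuals: %d DAE call(s), %d failed QC%s\n",
              nrow(df), calls, failed,
              if (x$no_background) " [no background subtraction]" else ""))
  if (length(x$qc_log))
    cat(sprintf("  %d QC log entr%s (see $qc_log)\n", length(x$qc_log),
                if (length(x$qc_log) == 1) "y" else "ies"))
  invisible(x)
}

#' @export
summary.dae_batch <- function(object, ...) {
  print(object)
  df <- as.data.frame(object)
  print(df[, c("sample_id", "status", "dae_percent", "p_value", "call", "nmd_class")],
        digits = 4)
  invisible(object)
}

#' @export
as.data.frame.dae_batch <- function(x, ...) {
  do.call(rbind, lapply(x$results, as.data.frame))
}
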