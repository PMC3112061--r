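# Classed conditions so callers (and analyze_batch QC) can distinguish a failed
# PCR / homozygous well from genuine input errors.

melt_error <- function(class, message, ...) {
  structure(
    class = c(class, "melt_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_peak_not_found <- function(window_label, window) {
  stop(melt_error(
    "melt_peak_not_found",
    sprintf("no local maximum in %s window [%.2f, %.2f] degC (failed PCR or homozygous sample?)",
            window_label, window[1], window[2]),
    window_label = window_label
  ))
}

stop_low_signal <- function(window_label, height, floor) {
  stop(melt_error(
    "melt_low_signal",
    sprintf("peak in %s window has height %.4g at or below the noise floor %.4g",
            window_label, height, floor),
    window_label = window_label, height = height, floor = floor
  ))
}
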