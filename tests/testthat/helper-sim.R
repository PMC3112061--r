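# Shared simulation shortcuts for the suite. The example allele windows
# ([50, 57] and [57.5, 64] degC around the default 54/60 Tm pair) are used
# throughout.

example_config <- function(...) {
  assay_config(markers = list(
    sim_snp = list(allele1_window = c(50, 57), allele2_window = c(57.5, 64))
  ), ...)
}

# A noise-free simulator configuration (still the default geometry).
noiseless_cfg <- function(...) {
  sim_config(noise_sd = 0, yield_cv = 0, rna_ratio_sd = 0, ...)
}

# Quantify one well through the full curve pipeline and return the ratio.
well_ratio <- function(curve, ntc = NULL, config = example_config()) {
  work <- if (is.null(ntc)) curve else subtract_background(curve, ntc)
  allelic_ratio(detect_peaks(derivative_curve(work, config), config))$ratio
}

# Simulate one individual's gDNA + cDNA (+ optionally puromycin) wells,
# quantify them, and return the dae_result. Lean loop used by the
# property-style tests; all randomness comes from the caller's RNG state.
sim_individual_result <- function(d = 0, carrier = d > 0, cfg = sim_config(),
                                  config = example_config(),
                                  with_puromycin = FALSE, n_reps = 4L) {
  ntc <- simulate_ntc(cfg)
  ratios <- function(ab, jitter) {
    vapply(seq_len(n_reps), function(r)
      well_ratio(simulate_well(ab, cfg, replicate = r,
                               ratio_jitter_sd = jitter), ntc, config),
      numeric(1))
  }
  g <- ratios(c(0.5, 0.5), 0)
  cc <- ratios(c(0.5, 0.5 * (1 - d)), cfg$rna_ratio_sd)
  pp <- if (with_puromycin)
    ratios(c(0.5, 0.5 * (1 - d * (1 - cfg$puromycin_rescue))), cfg$rna_ratio_sd)
  dae_test(g, cc, puromycin = pp, config = config, sample_id = "SIM")
}
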