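# Synthetic SimpleProbe melt experiment. Each allele contributes a two-state
# logistic melting transition at its own Tm; abundances scale the transition
# amplitudes, so derivative peak heights are proportional to allele abundance
# (closed form Y*A*a/(4s) for well-separated transitions). The generator
# reproduces the observables the assay relies on - two separable derivative
# peaks, allele-specific fluorescence yield bias, NMD-driven degradation of
# one allele in carrier cDNA and its partial rescue by puromycin - not the
# underlying PCR or hybridization thermodynamics.

#' Simulator configuration
#'
#' @param tm1,tm2 Allele melting temperatures in degC (probe-matched vs
#'   one-mismatch duplex; default 54 and 60, a typical SimpleProbe Tm gap).
#' @param s Transition width in degC (logistic scale parameter; default 1.0,
#'   i.e. ~3.5 degC full width at half maximum on the derivative peak).
#' @param grid `c(from, to, by)` temperature scan in degC (default 35-75 by
#'   0.1, the instrument's melting ramp).
#' @param amplitude Base fluorescence drop per unit abundance, in arbitrary
#'   units (default 100).
#' @param kappa Allele-2 fluorescence-yield factor (default 0.8): the
#'   mismatched duplex quenches differently, so even a 1:1 genomic sample
#'   gives peak-height ratios away from unity. Cancelled downstream by the
#'   gDNA normalization.
#' @param baseline `c(intercept, slope)` of the linear background
#'   fluorescence (default `c(20, -0.05)` a.u., a.u./degC).
#' @param noise_sd Additive Gaussian measurement noise per reading, in a.u.
#'   (default 0.05, i.e. 0.05% of the base amplitude - high-resolution
#'   instruments are very quiet; the derivative filter amplifies whatever is
#'   there).
#' @param yield_cv Per-replicate lognormal coefficient of variation of the
#'   overall amplification yield (default 0.10). Scales both peaks equally,
#'   so it cancels in every ratio.
#' @param rna_ratio_sd Per-replicate standard deviation of the log allelic
#'   ratio in RNA-derived wells (cDNA and puromycin cDNA; default 0.15).
#'   Models reverse-transcription/PCR template sampling: replicate mRNA
#'   ratios scatter noticeably more than genomic-DNA ratios, which only see
#'   measurement noise.
#' @param degradation Fraction `d` of the allele-2 transcript removed in
#'   carrier cDNA, in `[0, 1)` (default 0).
#' @param puromycin_rescue Fraction `rho` of the degradation reversed by
#'   puromycin NMD inhibition (default 0.9: rescue is partial, melting
#'   profiles tend toward the genomic profile without fully reaching it).
#' @param seed Optional integer seed; when set, the top-level simulation
#'   functions produce reproducible output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tm1 = 54, tm2 = 60, s = 1.0,
                       grid = c(35, 75, 0.1),
                       amplitude = 100, kappa = 0.8,
                       baseline = c(20, -0.05),
                       noise_sd = 0.05, yield_cv = 0.10,
                       rna_ratio_sd = 0.15,
                       degradation = 0, puromycin_rescue = 0.9,
                       seed = NULL) {
  if (!(tm1 < tm2)) stop("tm1 must be below tm2")
  if (length(grid) != 3L || grid[1] >= grid[2] || grid[3] <= 0)
    stop("grid must be c(from, to, by) with from < to and by > 0")
  if (tm1 < grid[1] || tm2 > grid[2]) stop("both Tm values must lie within the grid")
  if (s <= 0) stop("transition width s must be positive")
  if (kappa <= 0) stop("kappa must be positive")
  if (degradation < 0 || degradation >= 1) stop("degradation must be in [0, 1)")
  if (puromycin_rescue < 0 || puromycin_rescue > 1)
    stop("puromycin_rescue must be in [0, 1]")
  if (noise_sd < 0 || yield_cv < 0 || rna_ratio_sd < 0)
    stop("noise parameters must be non-negative")
  structure(
    list(tm1 = tm1, tm2 = tm2, s = s, grid = grid, amplitude = amplitude,
         kappa = kappa, baseline = baseline, noise_sd = noise_sd,
         yield_cv = yield_cv, rna_ratio_sd = rna_ratio_sd,
         degradation = degradation, puromycin_rescue = puromycin_rescue,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  Tm %.1f / %.1f degC, width %.2f degC, grid %.0f-%.0f by %.2f\n",
              x$tm1, x$tm2, x$s, x$grid[1], x$grid[2], x$grid[3]))
  cat(sprintf("  amplitude %g a.u., kappa %.2f, baseline (%g, %g)\n",
              x$amplitude, x$kappa, x$baseline[1], x$baseline[2]))
  cat(sprintf("  noise_sd %g, yield_cv %g, rna_ratio_sd %g\n",
              x$noise_sd, x$yield_cv, x$rna_ratio_sd))
  cat(sprintf("  degradation %g, puromycin rescue %g\n",
              x$degradation, x$puromycin_rescue))
  invisible(x)
}

sim_grid <- function(cfg) seq(cfg$grid[1], cfg$grid[2], by = cfg$grid[3])

#' Assay configuration matching a simulator configuration
#'
#' Builds allele Tm windows bracketing the simulated transitions, split at
#' the midpoint between the two Tm values.
#'
#' @param cfg A [sim_config()].
#' @param marker_snp Marker name used on the simulated plates.
#' @param ... Passed to [assay_config()] (filter settings, thresholds, ...).
#' @return An [assay_config()].
#' @export
sim_assay_config <- function(cfg = sim_config(), marker_snp = "sim_snp", ...) {
  mid <- (cfg$tm1 + cfg$tm2) / 2
  markers <- list(list(
    allele1_window = c(max(cfg$grid[1], cfg$tm1 - 4), mid),
    allele2_window = c(mid + 0.5, min(cfg$grid[2], cfg$tm2 + 4)),
    allele1_label = "allele1", allele2_label = "allele2"))
  names(markers) <- marker_snp
  assay_config(markers = markers, ...)
}

#' Simulate one well's melting curve
#'
#' `F(T) = baseline(T) + Y * A * (a1 * sigma((tm1 - T)/s) +
#' kappa * a2 * sigma((tm2 - T)/s)) + eps(T)` with `sigma` the standard
#' logistic, `Y` a lognormal per-replicate yield factor and `eps` iid
#' Gaussian measurement noise.
#'
#' @param abundances `c(a1, a2)`, non-negative allele template abundances
#'   with `a1 + a2 > 0`.
#' @param cfg A [sim_config()].
#' @param well_id,sample_id,material,replicate,marker_snp Curve annotation.
#' @param ratio_jitter_sd Extra per-replicate lognormal jitter of the
#'   allelic ratio (sd of the log ratio), applied symmetrically to the two
#'   abundances. Used by [simulate_individual()] for RNA-derived wells.
#' @param seed Optional seed for this single well (bitwise-reproducible
#'   output).
#' @return A [melt_curve()].
#' @export
simulate_well <- function(abundances, cfg = sim_config(),
                          well_id = "W1", sample_id = "S1",
                          material = "gDNA", replicate = 1L,
                          marker_snp = "sim_snp",
                          ratio_jitter_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- as.numeric(abundances)
  if (length(a) != 2L || any(a < 0)) stop("abundances must be two non-negative numbers")
  if (sum(a) <= 0) stop("abundances must not both be zero")
  if (ratio_jitter_sd > 0) {
    eta <- stats::rnorm(1, 0, ratio_jitter_sd)
    a <- a * exp(c(-eta / 2, eta / 2))
  }
  temp <- sim_grid(cfg)
  y <- exp(stats::rnorm(1, 0, cfg$yield_cv))
  sigma1 <- stats::plogis((cfg$tm1 - temp) / cfg$s)
  sigma2 <- stats::plogis((cfg$tm2 - temp) / cfg$s)
  f <- cfg$baseline[1] + cfg$baseline[2] * temp +
    y * cfg$amplitude * (a[1] * sigma1 + cfg$kappa * a[2] * sigma2) +
    stats::rnorm(length(temp), 0, cfg$noise_sd)
  melt_curve(well_id = well_id, sample_id = sample_id, material = material,
             replicate = replicate, marker_snp = marker_snp,
             temperatures = temp, fluorescence = f)
}

#' Simulate a no-template control well
#' @inheritParams simulate_well
#' @return A [melt_curve()] with material `NTC`.
#' @export
simulate_ntc <- function(cfg = sim_config(), well_id = "NTC1",
                         marker_snp = "sim_snp", replicate = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  temp <- sim_grid(cfg)
  f <- cfg$baseline[1] + cfg$baseline[2] * temp +
    stats::rnorm(length(temp), 0, cfg$noise_sd)
  melt_curve(well_id = well_id, sample_id = "NTC", material = "NTC",
             replicate = replicate, marker_snp = marker_snp,
             temperatures = temp, fluorescence = f)
}

#' Simulate all wells of one heterozygous individual
#'
#' Produces `n_replicates` wells each of genomic DNA, untreated cDNA and
#' puromycin-treated cDNA. Genomic DNA always has abundances (0.5, 0.5). In a
#' carrier, NMD removes a fraction `d` of the allele-2 transcript in
#' untreated cDNA, of which puromycin restores the fraction
#' `cfg$puromycin_rescue`:
#' cDNA `(0.5, 0.5 * (1 - d))`, puromycin
#' `(0.5, 0.5 * (1 - d * (1 - rho)))`. RNA-derived wells additionally carry
#' the per-replicate allelic-ratio jitter `cfg$rna_ratio_sd`.
#'
#' @param sample_id Individual identifier.
#' @param carrier Logical: does this individual carry the NMD-triggering
#'   mutation on allele 2?
#' @param d Degradation fraction for carriers (defaults to
#'   `cfg$degradation`); for non-carriers a non-zero `d` is ignored with a
#'   warning.
#' @param cfg A [sim_config()].
#' @param n_replicates Replicates per material (default 4).
#' @param marker_snp Marker name.
#' @param well_ids Optional character vector of `3 * n_replicates` well ids
#'   (default: generated from the sample id).
#' @param seed Optional seed.
#' @return A list with `curves` (list of [melt_curve()]) and `layout_rows`
#'   (data.frame in sample-sheet form).
#' @export
simulate_individual <- function(sample_id, carrier = FALSE, d = cfg$degradation,
                                cfg = sim_config(), n_replicates = 4L,
                                marker_snp = "sim_snp", well_ids = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!carrier && d > 0) {
    warning("degradation d ignored for non-carrier ", sample_id)
    d <- 0
  }
  if (d < 0 || d >= 1) stop("degradation d must be in [0, 1)")
  rho <- cfg$puromycin_rescue
  spec <- list(
    gDNA = list(ab = c(0.5, 0.5), jitter = 0),
    cDNA = list(ab = c(0.5, 0.5 * (1 - d)), jitter = cfg$rna_ratio_sd),
    cDNA_puromycin = list(ab = c(0.5, 0.5 * (1 - d * (1 - rho))),
                          jitter = cfg$rna_ratio_sd))
  n_wells <- 3L * n_replicates
  if (is.null(well_ids)) {
    well_ids <- paste0(sample_id, "_", rep(c("g", "c", "p"), each = n_replicates),
                       rep(seq_len(n_replicates), times = 3L))
  } else if (length(well_ids) != n_wells) {
    stop("need ", n_wells, " well ids")
  }
  curves <- vector("list", n_wells)
  rows <- vector("list", n_wells)
  k <- 0L
  for (mat in names(spec)) {
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      curves[[k]] <- simulate_well(spec[[mat]]$ab, cfg,
                                   well_id = well_ids[k], sample_id = sample_id,
                                   material = mat, replicate = r,
                                   marker_snp = marker_snp,
                                   ratio_jitter_sd = spec[[mat]]$jitter)
      rows[[k]] <- data.frame(well = well_ids[k], sample_id = sample_id,
                              material = mat, replicate = r,
                              marker_snp = marker_snp, stringsAsFactors = FALSE)
    }
  }
  list(curves = curves, layout_rows = do.call(rbind, rows))
}

#' Simulate the homozygote mixing series
#'
#' One well set per mixing proportion, with abundances `(p, 1 - p)` per the
#' listed allele-1 proportions (so the expected allele-2 fraction is
#' `1 - p`). These are genomic-DNA mixtures of the two opposite homozygotes:
#' no RNA jitter applies.
#'
#' @param proportions Allele-1 proportions of the mixture points (default
#'   0.9, 0.8, ..., 0.1: the 9:1 through 1:9 series).
#' @param n_reps Replicates per point (default 4).
#' @param cfg A [sim_config()].
#' @param n_ntc Number of NTC wells appended (default 2).
#' @param marker_snp Marker name.
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return A list with `curves` (sample wells then NTCs), `layout`
#'   (a [plate_layout()]), `expected_fractions` (allele-2 fractions, one per
#'   point) and `point_ids` (the per-point sample ids, aligned with
#'   `expected_fractions`).
#' @export
simulate_mixing_series <- function(proportions = seq(0.9, 0.1, by = -0.1),
                                   n_reps = 4L, cfg = sim_config(),
                                   n_ntc = 2L, marker_snp = "sim_snp",
                                   seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (any(proportions <= 0 | proportions >= 1))
    stop("all proportions must be strictly in (0, 1)")
  curves <- list()
  rows <- list()
  point_ids <- sprintf("mix_%02.0f_%02.0f", 10 * proportions, 10 * (1 - proportions))
  for (i in seq_along(proportions)) {
    p <- proportions[i]
    for (r in seq_len(n_reps)) {
      wid <- sprintf("%s_r%d", point_ids[i], r)
      curves[[length(curves) + 1L]] <-
        simulate_well(c(p, 1 - p), cfg, well_id = wid, sample_id = point_ids[i],
                      material = "gDNA", replicate = r, marker_snp = marker_snp)
      rows[[length(rows) + 1L]] <-
        data.frame(well = wid, sample_id = point_ids[i], material = "gDNA",
                   replicate = r, marker_snp = marker_snp,
                   stringsAsFactors = FALSE)
    }
  }
  for (j in seq_len(n_ntc)) {
    wid <- paste0("NTC", j)
    curves[[length(curves) + 1L]] <- simulate_ntc(cfg, well_id = wid,
                                                  marker_snp = marker_snp,
                                                  replicate = j)
    rows[[length(rows) + 1L]] <-
      data.frame(well = wid, sample_id = "NTC", material = "NTC",
                 replicate = j, marker_snp = marker_snp, stringsAsFactors = FALSE)
  }
  layout <- suppressWarnings(plate_layout(do.call(rbind, rows),
                                          expected_replicates = n_reps))
  list(curves = curves, layout = layout,
       expected_fractions = 1 - proportions, point_ids = point_ids)
}

well_positions_96 <- function() {
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
}

#' Simulate a cohort of heterozygous individuals in plate batches
#'
#' Individuals are packed 8 per 96-well batch (4 replicates each of gDNA,
#' cDNA and puromycin cDNA = 12 wells per individual; the last batch may be
#' partial), with NTC wells appended to every batch. Carriers draw their
#' degradation fraction uniformly from `d_range`.
#'
#' @param n_individuals Number of heterozygous individuals (default 41).
#' @param carrier_ids Character vector of carrier sample ids, or `NULL` to
#'   draw `n_carriers` at random.
#' @param n_carriers Number of carriers drawn when `carrier_ids` is `NULL`
#'   (default 4).
#' @param d_range Range of the carrier degradation fraction (default
#'   `c(0.37, 0.60)`).
#' @param cfg A [sim_config()].
#' @param batch_size Individuals per batch (default 8).
#' @param n_ntc NTC wells per batch (default 2).
#' @param marker_snp Marker name.
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @return A list with `batches` (each a list of `curves` and `layout`) and
#'   `manifest` (data.frame of per-individual ground truth: sample_id,
#'   carrier, d, batch).
#' @export
simulate_cohort <- function(n_individuals = 41L, carrier_ids = NULL,
                            n_carriers = 4L, d_range = c(0.37, 0.60),
                            cfg = sim_config(), batch_size = 8L, n_ntc = 2L,
                            marker_snp = "sim_snp", seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  sample_ids <- sprintf("LCL%03d", seq_len(n_individuals))
  if (is.null(carrier_ids)) {
    carrier_ids <- sample(sample_ids, n_carriers)
  } else if (!all(carrier_ids %in% sample_ids)) {
    stop("carrier_ids must be a subset of the cohort sample ids")
  }
  is_carrier <- sample_ids %in% carrier_ids
  d <- ifelse(is_carrier, stats::runif(n_individuals, d_range[1], d_range[2]), 0)
  batch_of <- ceiling(seq_len(n_individuals) / batch_size)
  positions <- well_positions_96()

  batches <- vector("list", max(batch_of))
  for (b in seq_len(max(batch_of))) {
    members <- which(batch_of == b)
    curves <- list()
    rows <- list()
    for (j in seq_along(members)) {
      i <- members[j]
      wells <- positions[((j - 1L) * 12L + 1L):(j * 12L)]
      ind <- simulate_individual(sample_ids[i], carrier = is_carrier[i],
                                 d = d[i], cfg = cfg, marker_snp = marker_snp,
                                 well_ids = wells)
      curves <- c(curves, ind$curves)
      rows[[j]] <- ind$layout_rows
    }
    for (k in seq_len(n_ntc)) {
      wid <- paste0("NTC", k)
      curves[[length(curves) + 1L]] <- simulate_ntc(cfg, well_id = wid,
                                                    marker_snp = marker_snp,
                                                    replicate = k)
      rows[[length(rows) + 1L]] <-
        data.frame(well = wid, sample_id = "NTC", material = "NTC",
                   replicate = k, marker_snp = marker_snp,
                   stringsAsFactors = FALSE)
    }
    layout <- suppressWarnings(plate_layout(do.call(rbind, rows)))
    batches[[b]] <- list(curves = curves, layout = layout)
  }
  list(batches = batches,
       manifest = data.frame(sample_id = sample_ids, carrier = is_carrier,
                             d = d, batch = batch_of, stringsAsFactors = FALSE))
}
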