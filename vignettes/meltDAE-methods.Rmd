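---
title: "Measuring differential allelic expression from melting curves: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring differential allelic expression from melting curves: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltDAE)
```

## The measurement model

A SimpleProbe assay interrogates one exonic marker SNP in a heterozygous
individual. The probe fully matches one allele and mismatches the other, so
the probe–amplicon duplexes dissociate at two distinct melting temperatures
Tm₁ < Tm₂. While the instrument ramps temperature (35–75 °C in 0.1 °C
steps), fluorescence falls in two sigmoid transitions; on the negative
derivative −dF/dT each transition becomes a peak, and for well-separated
transitions the peak height is proportional to the abundance of the
corresponding allelic template. The per-replicate observable is the height
ratio $r = h_2/h_1$.

Two nuisance factors structure the whole design:

* **Fluorescence-yield bias.** The matched and mismatched duplexes quench
  the probe differently, so even a genomic-DNA sample with perfectly equal
  allele dosage gives $r \ne 1$ (a multiplicative factor $\kappa$). Because
  the same $\kappa$ applies to cDNA, the *difference of log ratios*
  cancels it exactly. This is why the estimator is
  $\Delta = \overline{\ln r}_\mathrm{cDNA} - \overline{\ln r}_\mathrm{gDNA}$:
  genomic DNA acts as each sample's internal 1:1 control.
* **Replicate scatter.** Genomic-DNA ratios are very reproducible; mRNA
  ratios scatter more (reverse-transcription and PCR sample a finite number
  of templates, and a degraded allele can be at genuinely low copy number).
  The statistics therefore work on the *replicate* log ratios (4 independent
  PCRs per material by default) rather than on a single averaged curve.

The point estimate is reported on a percent scale,
$\mathrm{dae\%} = 100\,(1 - e^{-|\Delta|})$: the fraction by which the
lower-expressed allele's transcript pool is reduced relative to the other
allele. Under the generative model below, degrading a fraction $d$ of one
allele's transcripts gives $\mathrm{dae\%} = 100d$ (up to the small peak
cross-talk discussed under *Numerical behaviour*), which makes the scale
directly interpretable: a 50% NMD knockdown reads as 50.

### Calling criteria

DAE is called only when all three hold:

1. magnitude: $\mathrm{dae\%} > 20$ (threshold configurable);
2. significance: two-sample t-test on the replicate log ratios, $p \le 0.05$;
3. interval: the 95% CI on $\Delta$ excludes 0.

The conjunction is deliberately conservative — the magnitude criterion
filters statistically significant but biologically trivial imbalances, so
the null false-call rate is far below the nominal $\alpha$ (measured < 0.2%
in the validation suite's 1000-individual null cohort).

### Which t-test?

`dae_estimate()` defaults to the **Welch** t-test, with the pooled Student
test available via `assay_config(var_equal = TRUE)`. The choice matters
because the design is intrinsically variance-heterogeneous: gDNA replicate
log ratios have much smaller dispersion than cDNA ones. With 4 + 4
replicates, a pooled test then effectively runs on ~3 degrees of freedom
while claiming 6, and its confidence intervals undercover (≈ 90% observed
at nominal 95% in simulation); Welch restores near-nominal coverage. Welch
is also what R's `t.test()` does by default, i.e. what an R-based analysis
of this kind most plausibly computes in practice.

### NMD classification

Puromycin inhibits nonsense-mediated decay. Re-estimating DAE with
puromycin-treated cDNA in place of untreated cDNA distinguishes the two
biological explanations for a positive call: if the puromycin profile
returns to the genomic baseline (dae% at or below the threshold *and* CI
including 0) the imbalance was decay-driven (`nmd_consistent`); if it still
meets all three criteria, decay inhibition changed nothing and a
*cis*-regulatory cause is more plausible (`regulatory_consistent`);
anything in between is `indeterminate`. Negative untreated calls are
`no_dae` regardless of puromycin. Note the rule is a *consistency*
classification, not a test with controlled error rates: with partial rescue
(see below) a real residual imbalance of a few percent sits near the CI
criterion's boundary, and occasional `indeterminate` classifications of
true NMD carriers are expected behaviour, not failures.

## Signal processing

* **Background.** The no-template control is the local-background baseline;
  the pointwise mean is used when a plate carries several NTC wells, and
  curves on differing grids are linearly interpolated. Subtraction precedes
  differentiation because the baseline is a property of the raw signal.
  Without any NTC the batch is processed unsubtracted and flagged — a
  linear baseline only adds a constant to −dF/dT, which the window-relative
  peak heights largely ignore.
* **Derivative.** −dF/dT comes from a single Savitzky–Golay
  smoothing-plus-differentiation pass (`signal::sgolayfilt`), not
  smooth-then-difference: the combined filter is the same local
  least-squares polynomial fit and amplifies noise less. Defaults: window
  17 points (1.7 °C), order 3. On a 0.1 °C grid this resolves the ~3.5 °C
  FWHM of a 1 °C-wide logistic transition (peak attenuation 0.09%) while
  keeping the derivative-noise contribution to peak heights small; an
  11-point window doubles a subtle bias discussed below, a 25-point window
  starts to clip the peak (0.4%). Near the series edges the polynomial is
  fitted on the full first/last window and evaluated off-centre, so
  polynomials up to the filter order are reproduced exactly everywhere.
* **Peaks.** Within each allele's Tm window the highest strict local
  maximum is taken, ties broken toward the window centre; the height is the
  smoothed derivative value at that grid point (a 3-point parabolic
  refinement is available but off by default — heights, not sub-grid Tm
  precision, drive the assay). Windows with no local maximum raise
  `melt_peak_not_found` (failed PCR, or a homozygous sample that has no
  second transition); peaks at or below 3× the MAD of the derivative
  outside both windows raise `melt_low_signal`. Both exclude the well with
  a QC log entry rather than poisoning the individual's estimate;
  individuals keeping fewer than 2 usable replicates of gDNA or cDNA are
  reported as failed.

## The synthetic generator

`simulate_well()` draws
$F(T) = b_0 + b_1 T + Y A\,[a_1 \sigma((T_{m1}-T)/s) + \kappa a_2
\sigma((T_{m2}-T)/s)] + \varepsilon(T)$
with $\sigma$ the standard logistic, $Y$ a lognormal per-replicate yield
factor (CV 0.10; cancels in every ratio) and $\varepsilon$ iid Gaussian
measurement noise. Defaults: Tm 54/60 °C (a typical matched/one-mismatch
probe gap of 6 °C), width $s = 1$ °C, amplitude 100 a.u., $\kappa = 0.8$,
baseline $20 - 0.05T$, noise sd 0.05 a.u.

Two dispersion parameters deserve comment, since the instruments' noise is
not published and had to be fixed by the package's own calibration:

* `noise_sd = 0.05` a.u. (0.05% of amplitude). The derivative filter
  amplifies additive noise by roughly 13× at these settings, so this choice
  puts ~1–3% noise on individual peak heights — consistent with an assay
  whose genomic-DNA ratios are described as highly reproducible. Much
  larger values are incompatible with the assay's published behaviour: the
  smallest mixing-series peak (9:1 point) is only ~2 a.u./°C high and
  drowns, and peak-height reading acquires a selection bias (below).
* `rna_ratio_sd = 0.15`: per-replicate sd of the log allelic ratio in
  RNA-derived wells only, applied symmetrically to the two template
  abundances. It models RT/PCR template sampling — the reason replicate
  mRNA ratios scatter more than DNA ratios — and it is what gives the
  t-test realistic replicate variance to work with. Genomic wells carry
  only measurement noise.

Carriers degrade a fraction $d$ of the allele-2 transcript in untreated
cDNA (`(0.5, 0.5(1-d))`); puromycin restores a fraction $\rho = 0.9$ of it
(`(0.5, 0.5(1-d(1-\rho)))`) — rescue is deliberately partial, matching
profiles that tend toward the genomic curve without reaching it. The cohort
generator packs 8 individuals × 12 wells into 96-well batches (the last
batch partial, 2 NTC wells appended per batch), draws carrier $d$ uniformly
from [0.37, 0.60], and emits the same file dialects the readers consume.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: PCR amplification kinetics and
asymmetric-PCR strand ratios; temperature-correlated drift or well-position
effects (noise is iid); probe-sequence–dependent Tm shifts (Tm values are
config constants); RNA-quality variation between samples; genuinely
homozygous or contaminated samples beyond the degenerate cases exercised in
tests.

## Numerical behaviour and edge cases

* **Peak cross-talk.** At ΔTm = 6 s the tail of each logistic transition
  adds ~1% of the *other* allele's amplitude to a peak. The validation
  suite therefore checks measured ratios against the exact two-logistic
  oracle (agreement ≤ 1%), and against the plain amplitude ratio only
  within its analytic validity region (ratios in [1/2, 2]: ≤ 2%). End to
  end, cross-talk biases dae% low by up to ~1.1 points at $d = 0.7$; the
  estimator is not corrected for it, because on real data the equivalent
  correction would require the true transition shapes.
* **Noise-selection bias.** Reading the height at the *maximum* of a noisy
  curve selects positive noise, inflating small peaks relatively more than
  large ones; it scales with derivative noise and motivated both the
  17-point window and the low `noise_sd` regime. At the defaults the
  residual recovery bias is about −1.4 dae points over $d \in [0.3, 0.7]$.
* **Degenerate variance.** If both replicate groups have zero variance the
  t-test is undefined; the estimate then reports $p = 0$ (or $p = 1$ when
  $\Delta = 0$) with a point interval and a `degenerate_variance` flag.
  This keeps the criteria well-defined for idealized noise-free input,
  where calling reduces to the magnitude threshold alone — which is also
  how the boundary behaviour (flip strictly above dae% = 20) is verified.
* **Orientation.** Allele 1 is the lower-Tm allele by window construction;
  all statistics use $|\Delta|$, so relabelling the alleles (every ratio
  inverted) flips the sign of $\Delta$ and changes nothing else.
* **Multiple testing.** Calling is per-individual, as the three-criteria
  rule defines it; an optional Benjamini–Hochberg mode
  (`bh_correction = TRUE`) is available for cohort screens and only ever
  removes calls.
* **Mixing regression.** The calibration line is fitted on fractions
  $h_2/(h_1+h_2)$ versus expected fractions — bounded, and exactly linear
  in the mixture proportion when yields are equal — with raw-ratio
  regression available by config. With $\kappa \ne 1$ the observed
  fractions follow a slightly curved Möbius function of the expected ones;
  the OLS R² of the default simulator series remains ≈ 0.997.

## Validation problem sizes

The test suite validates the filter against a brute-force sliding
least-squares oracle and both t flavours against textbook formulas
(≤ 1e-10); property checks run 200 simulated carriers (recovery bias and CI
coverage), 1000 simulated null individuals (specificity), a full seeded
41-individual cohort, and the 9 × 4-well mixing series, all in a few tens
of seconds on one CPU. Two boundary-sensitive checks are worth knowing
about when re-running with other seeds: observed CI coverage over 200
carriers has a sampling sd of ~1.7 percentage points around its true ≈ 94%,
and the all-carriers-`nmd_consistent` cohort outcome is a ~70–90%
probability event per cohort draw because partial rescue leaves a real
residual imbalance near the classification boundary (see *NMD
classification* above).

## Known limitations

* Quantification is by peak height only; no peak-area option.
* No correction for peak cross-talk or for the noise-selection bias (both
  ≲ 1.5 dae points at defaults; negligible against the 20-point threshold).
* The melt model is phenomenological (two-state logistic), not
  thermodynamic; Tm windows must be supplied per marker, not predicted.
* Proprietary instrument binaries are not parsed — export to delimited
  text is assumed.
* The NMD classification is rule-based and inherits the CI criterion's
  sensitivity to replicate dispersion near full rescue.
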