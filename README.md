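# meltDAE

Differential allelic expression (DAE) from probe-based high-resolution
melting (HRM) curves.

## The problem

In a heterozygous individual the two alleles of a gene should be expressed
1:1 unless something — a truncating mutation triggering nonsense-mediated
mRNA decay (NMD), a *cis*-regulatory variant, an epigenetic mark — skews the
balance. A sensitive way to detect such skew is to compare the two alleles
*within* one sample, so that every *trans*-acting and environmental factor
cancels. HRM with a single allele-specific hybridization probe (SimpleProbe)
does this cheaply: the probe melts off the matched and the mismatched allele
at two distinct temperatures, and on the smoothed negative-derivative plot
(−dF/dT vs T) each allele appears as a peak whose height tracks the
abundance of its template.

`meltDAE` turns exported melt tables into DAE calls:

1. **Background**: the no-template control (NTC) is subtracted from every
   well (pointwise mean when a plate carries several NTCs).
2. **Derivative**: −dF/dT is computed in one combined Savitzky–Golay
   smoothing + differentiation pass (default 17-point window, cubic).
3. **Peaks**: within each allele's configured Tm window the highest local
   maximum is taken; the per-replicate allelic ratio is the height ratio
   *r* = h₂/h₁.
4. **Normalization and test**: with replicate log ratios of cDNA and of
   genomic DNA (gDNA — the built-in 1:1 control that cancels any
   allele-specific fluorescence-yield bias κ), the DAE estimate is

   Δ = mean ln r(cDNA) − mean ln r(gDNA),  dae% = 100·(1 − e^{−|Δ|}),

   tested with a two-sample t-test on the replicate log ratios (Welch by
   default) and a confidence interval on Δ.
5. **Call**: DAE requires all three of (i) dae% > 20, (ii) p ≤ 0.05,
   (iii) the 95% CI on Δ excluding 0.
6. **NMD classification**: the estimate is recomputed with cDNA from
   puromycin-treated cells (puromycin inhibits NMD). If the puromycin
   profile resembles gDNA (dae% ≤ threshold, CI includes 0) the call is
   `nmd_consistent`; if the imbalance persists through all three criteria it
   is `regulatory_consistent`; otherwise `indeterminate`.

A full synthetic generator (`sim_config()`, `simulate_well()`,
`simulate_individual()`, `simulate_mixing_series()`, `simulate_cohort()`)
stands in for the instrument: two-state logistic melt transitions at the two
allele Tm values, allele-specific yield bias, replicate noise, NMD
degradation *d* of one allele in carrier cDNA and its partial puromycin
rescue (ρ = 0.9).

## Worked example

Small synthetic fixture files ship with the package (one NMD carrier with
allele-2 degradation d = 0.5: 4 PCR replicates each of gDNA, cDNA and
puromycin cDNA, plus 2 NTC wells):

```r
library(meltDAE)
config <- read_assay_config(system.file("extdata", "assay_config.yaml", package = "meltDAE"))
layout <- read_sample_sheet(system.file("extdata", "synthetic_carrier_samples.csv", package = "meltDAE"))
curves <- read_melt_table(system.file("extdata", "synthetic_carrier_melt.csv", package = "meltDAE"), layout)
batch  <- analyze_batch(curves, layout, config)
summary(batch$results[["LCL001"]])
```

prints

```
<dae_result> LCL001 (sim_snp)
  mean log ratio: gDNA -0.2143 (n=4) | cDNA -0.7948 (n=4) | puromycin -0.2950 (n=4)
  delta = -0.5805  DAE = 44.0%  95% CI [-0.7358, -0.4251]
  t = -11.660 (df 3.11), p = 0.00114
  criteria: magnitude TRUE | p-value TRUE | CI TRUE  ->  call: DAE (nmd_consistent)
  puromycin estimate:
    delta = -0.0807  DAE = 7.7%  CI [-0.2759, 0.1146], p = 0.283
```

Reading it: gDNA ratios sit at ln κ ≈ −0.21 (probe yield bias, not biology);
cDNA ratios are a further 0.58 log units down, i.e. the allele-2 transcript
is reduced ~44% — called as DAE. After puromycin the profile returns to the
genomic baseline (7.7%, CI spanning 0), so the imbalance behaves like NMD,
as expected for a truncating-mutation carrier.

`mixing_series_fit()` handles the other validation experiment — a titration
of the two opposite homozygotes (9:1 … 1:9) whose observed allele-2
fractions h₂/(h₁+h₂) must be linear in the expected ones:

```r
series <- simulate_mixing_series(cfg = sim_config(), seed = 42)
# quantify wells, then:
# fit <- mixing_series_fit(series$expected_fractions, measured)
# print(fit)   ->  observed = -0.0207 + 0.9615 * expected,  R^2 = 0.9968
```

## File formats

* **Melt table** (CSV/TSV, auto-detected): first column `Temperature`, one
  column per well; `#` lines ignored. See
  `inst/extdata/synthetic_carrier_melt.csv`.
* **Sample sheet** (CSV/TSV): columns `well, sample_id, material, replicate,
  marker_snp`; materials `gDNA`, `cDNA`, `cDNA_puromycin`, `NTC`
  (case-insensitive, common aliases accepted). See
  `inst/extdata/synthetic_carrier_samples.csv`.
* **Assay config** (YAML/JSON): per-marker allele Tm windows plus filter and
  threshold settings. See `inst/extdata/assay_config.yaml`.
* **Results table** (TSV, written by `write_results_table()`): one row per
  individual with replicate counts, mean log ratios per material, Δ, dae%,
  CI, t, p, the three criteria flags, the call and the NMD class;
  round-trips through `read_results_table()`.

A command-line wrapper (`inst/scripts/meltdae`) exposes the three
experiments as `call-dae`, `mix-validate` and `simulate` subcommands.

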