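Package: meltDAE
Title: Differential Allelic Expression from High-Resolution Melting Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies differential allelic expression (DAE) from probe-based
    high-resolution melting (HRM) curves. Melting transitions of the two alleles
    of a heterozygous marker SNP are converted into peaks on the smoothed
    negative-derivative plot (Savitzky-Golay filtering), the allelic ratio is
    measured as the ratio of the two peak heights, and the cDNA log ratio is
    normalized against the genomic DNA log ratio, which serves as an internal
    1:1 control for probe fluorescence-yield bias. Replicate log ratios are
    compared with a t-test, DAE is called by a three-criteria rule (magnitude,
    p-value, confidence interval), and puromycin-treated cDNA is used to
    classify calls as consistent with nonsense-mediated mRNA decay (NMD) or
    with a regulatory variant. Includes a synthetic melting-curve simulator
    (two-state logistic transitions with allele-specific Tm) for mixing-series
    calibration, single individuals, and plate-format cohorts, plus readers and
    writers for instrument-style melt tables, plate sample sheets and result
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
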