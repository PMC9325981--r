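# plasticdom

Plastics shed dissolved organic matter (DOM) as they weather. This leachate
is a mixture of additives, breakdown products and oligomers that
heterotrophic bacteria in surface waters can metabolise — but whether it
stimulates or suppresses bacterial growth depends on its molecular makeup
and on the carbon already present in the receiving water. `plasticdom` is an
R package for quantifying that interaction end to end: from
ultra-high-resolution mass spectra of DOM and raw bottle-incubation
measurements through to mixed-effects inference of treatment effects and
taxon-level associations. It is aimed at aquatic biogeochemists and
microbial ecologists who run leachate-addition (or any DOM-amendment)
experiments across many lakes or sites.

## What it computes

**Molecular formula assignment (chem).** Negative-mode FT-ICR-MS peak lists
are assigned isotope-free CHNOS formulas by exhaustive search within element
bounds, keeping candidates whose [M−H]⁻ ion matches the measured m/z within
a ppm tolerance (default 0.5 ppm) and passing plausibility filters: 0 ≤ H:C
≤ 2.5, 0 ≤ O:C ≤ 1.2, DBE = C − H/2 + N/2 + 1 ≥ 0, and an even-electron
anion parity constraint. Blank correction removes formulas on identity.

**DOM composition statistics (dom_metrics).** For each sample's formula
table with normalised intensities *pᵢ*:

- functional diversity as Rao quadratic entropy on carbon number,
  FD = Σᵢ Σⱼ pᵢ pⱼ |Cᵢ − Cⱼ| (ordered pairs), a measure of molecular-size
  diversity;
- the high-lability fraction, classifying formulas with H:C ≥ 1.5 as likely
  bioavailable, both as a count fraction and as the share of normalised
  intensity;
- unique-formula analysis against reference samples, and cross-referencing
  of unique formulas against a packaged table of known plastic additives.

**Bacterial metabolism (metabolism).** Raw incubation records become rates:
bacterial protein production (BPP, µg C L⁻¹ h⁻¹) from ³H-leucine
scintillation counts (live − killed − blank CPM, counting-efficiency
corrected, converted at 1.55 kg C per mol leucine); respiration from
oxygen-optode percent-saturation series (median of the last 10 stable
readings, Garcia–Gordon solubility, respiratory quotient 1); and bacterial
growth efficiency BGE = BPP / (BPP + respiration).

**Treatment inference (mixed_model).** Log-scale linear mixed models with a
lake random intercept, z-standardised covariates, Pearson-r > 0.90
collinearity screening, AIC backwards elimination (drop a term unless
keeping it improves AIC by 2 or more; the treatment term is never dropped),
and marginal treatment means, fold changes and ±1 SD moderator probing with
Wald 95% intervals, back-transformed by exponentiation.

**ASV associations (asv_assoc).** Shannon diversity, a <100-total-reads
filter, median-of-ratios size factors, per-ASV negative-binomial GLMs of
counts against a metabolic fold-change covariate (moment dispersion, Wald
t-test, slopes in log2 units), and Benjamini–Hochberg correction.

**Synthetic data (synthetic_data) and pipeline.** Every input the pipeline
consumes can be generated with known ground truth at the study scale
(29 lakes × 2 treatments; DOM for 22 lakes, 16S for 20, respiration for 18),
so the whole analysis is testable offline, and `run_pipeline()` executes all
stages from one seeded configuration.

## Worked example

```r
library(plasticdom)

# assign formulas to three measured peaks
peaks <- data.frame(mz = c(165.01933, 329.17583, 413.08726),
                    intensity = c(5.2, 1.4, 3.1))
hits <- assign_formulas(peaks)
subset(hits, is_best, c(mz, formula, mass_error_ppm))
#>         mz      formula mass_error_ppm
#> 1 165.0193       C8H6O4    0.013354920
#> 2 329.1758     C20H26O4    0.008643466
#> 3 413.0873 C13H22N2O11S   -0.256450078

# DOM composition of a small sample
leachate <- formula_table(c("C8H6O4", "C10H14O2", "C14H22O2", "C12H24O6"),
                          intensity = c(5.2, 1.4, 3.1, 8.0),
                          sample_id = "leachate")
functional_diversity(leachate)
#> [1] 2.343133
lability_summary(leachate)
#> $frac_count
#> [1] 0.5
#> $frac_intensity
#> [1] 0.6271186

# metabolic rates from raw measurements
bpp <- bpp_from_counts(cpm_live = 8100, cpm_killed = 40, cpm_blank = 30,
                       cpm_standard = 8e4, standard_dpm = 1e5,
                       specific_activity = 60)
resp <- respiration_rate(o2_start_mgL = 9.55, o2_end_mgL = 9.38,
                         duration_h = 72)
c(bpp = bpp, respiration = resp, bge = growth_efficiency(bpp, resp))
#>        bpp respiration        bge
#> 0.07786849  0.88626155 0.08076555
```

The first two peaks are isophthalic acid and dicyclohexyl phthalate — both
in the packaged plastic-additive reference (`plastic_additives()`). The
BPP/respiration pair above corresponds to a bacterial community allocating
about 8% of the carbon it processes to biomass.

A complete synthetic study runs in well under a minute:

```r
report <- run_pipeline(pipeline_config(seed = 1))
report$lmm$bpp$effects$fold   # treatment fold change with 95% CI
```

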