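---
title: "Methods: models, defaults and design choices in plasticdom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices in plasticdom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasticdom)
```

`plasticdom` quantifies how dissolved organic matter (DOM) leached from
plastics affects bacterial metabolism in lake surface waters. This vignette
is the package's own account of the methods: the models and their
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
design decisions taken where reasonable alternatives existed.

## Molecular formula assignment

Ultrahigh-resolution mass spectrometry of DOM resolves ion masses precisely
enough that elemental compositions can be assigned without structural
information. The package implements a deliberately transparent assignment
core: every CHNOS formula inside configurable element bounds (C 1–60,
H 1–120, N 0–4, O 0–40, S 0–2) is enumerated once per configuration, and a
measured peak is matched to every candidate whose [M−H]⁻ ion mass lies
within the ppm tolerance.

Plausibility filters reject chemically impossible or implausible
compositions:

* **H:C in [0, 2.5] and O:C in [0, 1.2]** — the occupied region of the van
  Krevelen plane for natural and plastic-derived organic matter.
* **DBE ≥ 0**, with DBE = C − H/2 + N/2 + 1, the ring-plus-double-bond
  count of the neutral.
* **Even-electron anion parity.** Deprotonation removes H⁺ from an
  even-electron neutral; the anion has an even electron count exactly when
  the neutral's H + N count is even. Odd-parity compositions would imply
  radical anions, which direct-infusion electrospray produces only
  marginally.

Candidates are ranked by absolute mass error, with ties broken by fewer
heteroatoms (N + S) and then lower DBE — a deterministic, chemically
conservative rule favouring CHO compositions, which dominate DOM. The
default tolerance of 0.5 ppm is typical of a well-calibrated 15 T
instrument; it is a configuration value, not a constant. The analytical
window defaults to the exported 150–1000 m/z range; a wider 150–2000 Da
preset can be set through `assignment_config(window = )` for spectra
described on that scale.

Isotopologue verification, adducts other than [M−H]⁻, multiple charging and
instrument calibration are out of scope: the package assumes calibrated,
singly-charged, deprotonated peak lists.

Blank correction is procedural, not subtractive: a formula detected in the
blank is removed from the sample outright. This matches how
presence/absence-based unique-formula arguments are made; intensity
subtraction would require cross-run intensity comparability that
direct-infusion data do not generally support.

## DOM composition statistics

**Functional diversity.** The diversity of potential substrate niches DOM
offers is summarised as Rao quadratic entropy on the carbon-atom number of
formulas: FD = Σᵢ Σⱼ pᵢ pⱼ |Cᵢ − Cⱼ| over all ordered pairs, where pᵢ are
sum-normalised peak intensities. The ordered-pair convention (each
unordered pair counted twice, the diagonal contributing zero) is stated
explicitly because halving conventions differ between implementations. The
implementation uses a sorted prefix-sum identity (O(n log n)); the test
suite checks it against the naive double loop to 10⁻¹⁰ up to n = 2000.
Intensity weighting is the default because diversity indices of this family
are abundance-weighted; a uniform-weight option exists because peak
intensity in electrospray is only a semi-quantitative abundance proxy, and
the choice between them is not neutral (both are reported by the demo
pipeline).

**Lability.** A formula is classed as having a high lability index when
H:C ≥ 1.5 (boundary inclusive): hydrogen-saturated molecules are on average
more energy-rich and more accessible to heterotrophs. A sample is
summarised by the fraction of formulas above the threshold and the fraction
of normalised intensity they carry; the normalisation basis is the
assigned, blank-corrected formula table.

**Unique formulas and additive matching.** Formulas unique to a target
sample are found by exact set difference against any number of reference
tables, reported with the unique percentage. Unique formulas are then
cross-referenced against a packaged table of 13 known plastic additives and
breakdown products. Matching is exact-formula only: two packaged rows share
C10H14O2, and both are always reported as candidate identities, because
formula-level data cannot separate isomers. Relative abundance of a match
is computed against the full sample, not the unique subset, so percentages
remain comparable across samples.

## Metabolic rates from raw measurements

**BPP.** The leucine-incorporation chain is
net CPM = max(0, live − killed − blank), DPM = net/efficiency with
efficiency = standard CPM / standard DPM (required in (0, 1]), moles of
leucine = DPM / (2.22×10¹² DPM Ci⁻¹ × specific activity), and carbon =
1.55 kg C per mol leucine. The 1.55 factor is the conventional
protein-synthesis conversion without isotope dilution; the added leucine
concentration is treated as saturating. Both are exposed as arguments
because lot-specific activity and dilution corrections vary between
laboratories. Negative net counts are clamped to zero with a warning —
field blanks occasionally out-count live samples, and a hard error would be
wrong there.

**Respiration.** Optode series report percent air saturation at 1 s
cadence with an equilibration transient. Stability is declared where a
rolling 10-point standard deviation stays at or below 0.1% saturation
(configurable; the value is an operational definition of "steady state"),
and the oxygen value is the median of the last 10 stable readings —
robust to single-reading spikes. Concentration conversion uses the
García–Gordon refit of the Benson–Krause solubility data, valid for
0–40 °C and 0–40 PSU, scaled linearly by barometric pressure; at 20 °C,
0 PSU and 1013.25 hPa, 100% saturation is 9.09 mg O₂ L⁻¹. Oxygen drawdown
converts to carbon with a respiratory quotient of 1 (configurable).
Negative drawdown (oxygen production) is clamped to zero with a warning,
consistent with dark incubations.

**BGE.** Growth efficiency is BPP / (BPP + respiration), undefined (NA)
when both are zero. Because the study design has three BPP bottles but a
single respiration vial pair per lake–treatment, BGE pairs the replicate
mean BPP with that one respiration estimate; this pairing rule lives in
`incubation_rates()`.

## Mixed-effects treatment inference

Metabolic responses are strictly positive and right-skewed, so inference is
on the natural-log scale: log y = treatment + covariates +
treatment×covariates + (1 | lake), with the lake random intercept absorbing
repeated measures of the same water. Covariates are z-standardised
internally, which makes "±1 SD" moderator probing exact and effect sizes
comparable; means and SDs are stored for back-transformation.

Model selection follows common field practice: ML fitting, pairwise Pearson
screening at |r| > 0.90 (strict) with the retained member chosen by a
priority order expressing biological relevance (DOM functional diversity
first, geographic position last — a user-supplied order, since "most
relevant" is a judgement), then backwards elimination in which the
droppable term whose removal gives the lowest AIC is removed, provided
that AIC is strictly below the current AIC + 2. Equivalently, a term is
retained only if keeping it improves AIC by at least 2; at the exact
boundary the term is retained. Marginality is respected (a main effect is
droppable only after its interaction) and the treatment term — the design
variable — is never eliminated. Ties are broken by fewer parameters, then
term name, making selection deterministic. The selected model is refit by
REML for reporting.

Marginal treatment means are computed at covariate means (all z-scores 0),
with moderator probing at −1/0/+1 SD, and back-transformed by
exponentiation; the fold change is exp(plastic − control contrast), so it
equals the ratio of back-transformed means exactly. Intervals are Wald
normal intervals on the log scale. Degrees-of-freedom corrections
(Satterthwaite, Kenward–Roger) were deliberately not implemented: with the
default design (29 lakes, 174 observations) the difference is small, and
the test suite verifies empirically that the Wald intervals cover the true
fold change in 93–97% of 1000 simulated studies. Coverage claims apply to
these intervals only.

## ASV association statistics

Community diversity uses the Shannon index in nats on unrarefied counts
(the log base and rarefaction policy are conventions; nats are the default
and the counts enter as-is). ASVs with fewer than 100 total reads across
samples are removed before association testing — rare taxa have noisy,
stochastic abundances — with an exactly-100-read ASV retained; a per-sample
variant of the filter is available.

Library-depth normalisation uses median-of-ratios size factors computed as
the exponentiated median of log count-to-geometric-mean ratios over ASVs
present in all samples (geometric averaging for even-length medians; this
matches the canonical estimator exactly, and the test suite cross-checks
against an independent implementation).

Each ASV is then fit with a negative-binomial GLM: log link, intercept plus
a per-sample covariate (the lake's log2 metabolic fold change), and the log
size factor as offset. Dispersion is estimated per ASV by the method of
moments on normalised counts, α = max((var − mean)/mean², 10⁻⁸) — the
floor makes near-Poisson ASVs reduce to an effectively Poisson fit. The
covariate slope is reported in log2 units, and the Wald statistic is
referred to a t distribution with n − 2 degrees of freedom: with ~20
samples the normal reference is visibly anticonservative, and the t
reference is the standard small-sample choice for per-feature GLMs. The
test suite verifies type-I error of 4–7% at nominal 5% under a Poisson
null and planted-slope recovery with controlled false discovery.

This is intentionally *not* a reimplementation of shrinkage-based
differential-abundance frameworks: there is no dispersion shrinkage across
features, no outlier replacement and no independent filtering. Those
components improve ranking stability on real data but obscure what is being
estimated; the package's plain per-ASV fit makes the association model
explicit, at the cost of less power for low-count ASVs. Consequently
absolute counts of "significant" ASVs are not comparable with
shrinkage-based analyses. Multiple testing uses Benjamini–Hochberg with
missing p-values passed through and excluded from the test count.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with known ground
truth, at the design scale of the emulated study: 29 lakes × 2 treatments,
DOM spectra for 22 lakes, 16S for 20, respiration for 18; 3 BPP bottles and
1 respiration vial pair per treatment. Covariates are uniform draws within
the surveyed field ranges (DOC 0.55–7.97 mg L⁻¹, pH 5.81–6.95, temperature
9.4–20.6 °C, FD 6.12–6.96, latitude 59.1–70.3° N, Shannon 3.46–6.38; total
nitrogen, for which no range was surveyed, defaults to 0.1–0.9 mg L⁻¹, a
typical oligo- to mesotrophic span). The default true effect sizes are the
emulated study's headline values — a 2.29× treatment fold on BPP, 1.72× on
BGE with a −0.34 per-SD FD interaction — and default noise levels
(lake SD 0.45, residual SD 0.35 on the log scale) give between-lake spread
of the magnitude such surveys show. These defaults are a *calibration* so
that the demo run is quantitatively familiar, not a validation against
field data.

Key constructions:

* **Formula universe.** Lake samples draw from a shared pool of CHO
  formulas (enumerated under the assignment filters, carbon counts weighted
  towards a broad profile), each lake receiving 3684–7116 formulas; the
  leachate (855 formulas after blank correction) takes 65% of its formulas
  from compositions present in at least one lake — drawn preferentially
  from a narrow carbon band, giving the leachate its characteristically low
  functional diversity — and 35% unique ones, always including the 13
  packaged additive formulas. Lability count fractions are constructed
  exactly (18.6% leachate, ~11.5% lakes), and leachate labile formulas get
  a 20× intensity boost so the labile fraction dominates normalised
  intensity (~80%), as real leachate shows. Peak lists perturb exact ion
  masses with 0.1 ppm Gaussian error. Blank contaminant formulas are
  injected into every sample so blank correction is exercised.
* **Incubations.** CPMs are generated by inverting the leucine arithmetic
  from true per-bottle BPP (with Poisson counting noise), and optode series
  from true respiration with an exponential equilibration transient and
  0.02%-saturation plateau noise. At zero noise the metabolism module
  recovers the true rates within 2%.
* **ASV tables.** NB counts (default dispersion 0.2) with log-normal
  baselines, 0.5–2× library-size variation, and a planted log2 slope on a
  chosen ASV fraction against the metabolic covariate. The default scale
  (300 ASVs × 20 samples) is a reduced emulation of the ~2000-ASV field
  scale, chosen so the full pipeline and its simulation-based tests run on
  a desktop in minutes; the full scale is available by argument.

What the generator does **not** emulate: mass-spectral noise physics beyond
Gaussian ppm error (no peak-picking artefacts, isotopologues or adducts),
spatial structure among lake covariates, phylogenetic correlation among
ASVs, or taxon-specific substrate preferences. Passing tests therefore
demonstrate that the pipeline's computations are correct and its inference
calibrated under its own model assumptions — not that those assumptions
hold in any particular field dataset.

## Numerical choices and degenerate inputs

* Assignment is exactly deterministic: ties in |ppm error| are broken by
  heteroatom count, DBE, then formula string.
* FD of an empty or single-formula table is 0; lability fractions of an
  empty table are 0; an all-zero-intensity table falls back to uniform
  weights.
* `unique_formulas` against an empty reference list returns the target
  whole (100% unique).
* Backward elimination compares AICs with strict inequality at the +2
  boundary; refitting the selected model reproduces its AIC to 10⁻⁸.
* A constant association covariate yields missing slopes and p-values
  rather than zeros; non-converged NB fits are flagged, not fatal.
* All generators are deterministic functions of (design, seed); the
  pipeline splits one root seed into fixed per-stage offsets so disabling
  one stage never changes another's numbers.

## Problem sizes used by the checks

The packaged verification suite runs the full default-scale pipeline
(22 lakes × ~3700–7100 formulas plus the 855-formula leachate, 174 BPP
bottles, 36 BGE observations, 300 ASVs × 20 samples), 1000 simulated
studies for interval coverage, 20 × 500 Poisson-null feature tests and 50
planted-slope simulations for association calibration, and brute-force
oracle comparisons up to n = 2000 (FD) and m = 1000 (Benjamini–Hochberg).
These sizes were chosen to make the statistical checks decisive while
keeping a complete run in the minutes range on a single core.

## Known limitations

* The chem module assigns formulas, not structures; additive matches are
  candidate identities.
* The CHNOS alphabet excludes phosphorus by default (every packaged
  additive is CHO); bounds are configurable but the enumeration cost grows
  with the alphabet.
* BGE inherits the single-respiration-vial design: no within-lake
  replication of respiration means BGE uncertainty is dominated by that one
  measurement.
* Wald intervals ignore degrees-of-freedom corrections; at many fewer than
  ~18 lakes they will undercover.
* The NB association model treats the per-lake fold change as a fixed
  covariate, ignoring its estimation error.
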