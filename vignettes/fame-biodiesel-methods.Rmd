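---
title: "From FAME profiles to biodiesel properties: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From FAME profiles to biodiesel properties: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fameprops)
```

`fameprops` implements the computational chain of a cultivation-optimization
study on an oleaginous diatom: fatty-acid composition in, biodiesel property
panel and culture analytics out. This vignette is the package's account of
the underlying models, the conventions they require, and the places where
the design was genuinely open.

## 1. Shorthand parsing and the composition model

A fatty acid is identified by the field's shorthand `C<carbons>:<double
bonds>` with an optional omega class (`n3` or `(n-3)` — both dialects occur
in GC-MS tables) and an optional trailing `t` for a trans isomer. The parser
is strict: a malformed code, a double-bond count exceeding `carbons/2`, or
an omega class longer than the chain is an error naming the offending token,
because a silently mis-parsed acid corrupts every downstream property.

A profile is an ordered list of (acid, mass % of total fatty acids). Two
conventions matter and are fixed deliberately:

* **"ND" (not detected) and blank cells are zero, not missing.** Published
  class totals and unsaturation values are sums over the detected acids;
  treating ND as `NA` would make those sums unreproducible. Every
  substitution is reported via `message()` so the record is visible.
* **Duplicate shorthand within a sample is an error, not a silent sum.**
  A GC-MS table lists each identified acid once; a duplicate means a data
  handling mistake upstream.

Class totals are plain sums by double-bond count: saturated (0),
monounsaturated (1), polyunsaturated (&ge; 2). Profiles store any *printed*
class totals separately from computation; `verify_class_totals()` compares
the two. In the packaged reference table the control MUFA total prints
36.12 % while its listed components sum to 32.09 % — one cell of the source
table is evidently blank — so that cell is flagged as a known discrepancy
and all computation uses the component sum.

## 2. The average degree of unsaturation

The central statistic is the mass-weighted double-bond count

$$\mathrm{ADU} = \sum_i N_i \, \mathrm{Mf}_i,$$

with $N_i$ the number of C=C double bonds and $\mathrm{Mf}_i$ the mass
fraction. Two choices deserve justification:

* **Mass fractions are percentages divided by 100, not renormalized to the
  identified total.** GC-MS tables rarely identify 100 % of the signal (the
  packaged profiles identify 76 % and 84 %). Dividing by the identified
  total is arguably more faithful to the oil, but dividing by 100 is the
  convention under which the published downstream property values are
  reproduced exactly, so it is the default; `adu(, renormalize = TRUE)`
  exposes the alternative. With renormalization the control profile's ADU
  moves from 0.785 to 78.53/75.96 &asymp; 1.034.
* **Geometry does not enter.** A trans double bond counts the same as a cis
  one: the statistic counts bonds, and the downstream correlations were
  fitted on that convention.

Although the statistic is sometimes labelled a percentage, its values for
algal oils sit around 0.5–1.1 and all downstream arithmetic consumes it as a
dimensionless fraction-weighted count; the package treats it as such.

## 3. The property correlations

Kinematic viscosity, specific gravity, cloud point, cetane number, iodine
value and higher heating value are affine functions of ADU (coefficients in
the README). They are empirical correlations fitted on FAME mixtures, valid
roughly for ADU in [0, 3]; a negative ADU is a domain error, and
extrapolation far above 3 is meaningless chemistry even though the functions
evaluate.

**The cloud-point coefficients are reconstructed.** The correlation as
printed in the source literature (`Cp = −3.35·ADU + 19.99`) cannot produce
the cloud points published alongside it: at the profile ADUs of 0.785 and
0.695 it gives 17.4–17.7 °C, while the published values are 9.51 and
10.71 °C. Back-solving every published (ADU, Cp) pair — four pairs across
two tables — yields a single consistent line with slope −13.356 and
intercept 19.994, which reproduces all four at 2 dp. The package therefore
defaults to the reconstructed coefficients (`cp_variant = "reconstructed"`),
keeps the printed ones selectable for fidelity, and records the variant in
every panel's provenance field. The two variants agree at ADU = 0 within
0.004 °C, so the reconstruction is a slope correction, not a refit.

Saponification value, long-chain saturation factor and cold filter plugging
point have no published correlation in the reference analysis, so the
standard literature forms are used (SV = &Sigma; 560·pctᵢ/MWᵢ with free-acid
molecular weights from a packaged lookup; LCSF = 0.1·C16:0 + 0.5·C18:0 +
1·C20:0 + 1.5·C22:0 + 2·C24:0; CFPP = 3.1417·LCSF − 16.477). Every report
marks these three as "literature-form, not paper-verified".

Compliance bounds are inclusive: EN 14214 requires CN &ge; 51, KV &isin;
[3.5, 5.0] mm²/s, IV &le; 120; ASTM D6751 requires CN &ge; 47, KV &isin;
[1.9, 6.0], density &isin; [0.86, 0.90]. Properties a standard does not
bound yield "not-applicable", never a failure.

**Reporting precision.** Composition inputs are printed at 2 dp, so
properties are compared at an absolute tolerance of ±0.02; full precision is
retained internally and rounding happens only at presentation.

## 4. Fucoxanthin and productivities

The dual-wavelength quantification `(6.39·A445 − 5.18·A663)` corrects the
fucoxanthin absorbance at 445 nm for chlorophyll interference at 663 nm. The
bracket is interpreted as mg of fucoxanthin per litre of extract at 1 cm
path; the content in mg/g DW then needs the extract volume and the extracted
dry mass. Because bench protocols state the extraction as a biomass:solvent
ratio and the formula itself omits the volume, `fucoxanthin_content()`
refuses to default it silently: the caller passes either `extract_volume_l`
or the ratio `ml_per_mg`. A negative bracket (chlorophyll-dominated extract)
clamps to zero with a warning rather than erroring — real extracts produce
it.

Productivity is the signed volumetric rate `(C₂ − C₁)/(t₂ − t₁)` in
mg/L/day. Per-mass contents (lipid, fucoxanthin in mg/g DW) are converted to
volumetric concentrations via the same-day dry weight, linearly interpolated
(with a note) when a day's dry weight is missing. The default window runs
from the first sampled day to the day of peak mean concentration, matching
how cultivation studies report headline rates at the growth peak; any window
is selectable. The published headline productivities themselves are mutually
inconsistent with the published concentrations under any single window (the
initial concentrations are unprinted), so the package demonstrates
productivity *ordering* across treatments and recovers exact values only on
synthetic data, where the truth is known.

## 5. Treatment comparison

Group comparisons follow the field's reporting style: one-way ANOVA
(`stats::aov`), and when it rejects at &alpha; = 0.05, all-pairs Tukey HSD
(`stats::TukeyHSD`) condensed into a compact letter display — groups sharing
a letter are not significantly different. Exactly two groups use Welch's
t-test. The post-hoc choice is the package's own: the reference analysis
names only "t-test and one-way ANOVA", and Tukey HSD is the standard
all-pairs companion whose letters match the figure annotations such studies
print. The letter display enumerates maximal cliques of the
non-significance graph (Bron–Kerbosch; treatment counts are small), ordered
by descending group mean, which guarantees that groups with disjoint letter
sets are significantly different on every pairwise test. All-identical data
(zero total variance) is reported as F = 0, p = 1, one shared letter, rather
than a 0/0 failure.

## 6. The synthetic experiment generator

The generator exists so that every analysis stage is testable against known
truth without external data. It emulates the study's factorial design
verbatim: sampling days 0, 2, 4, 6, 8, 10; triplicates; a 0–2 day lag; a
peak on day 8 with a slight post-peak decline. Its trajectory model is

* **biomass**: inoculum-anchored lag, then a logistic rise rescaled to hit
  the carrying capacity *exactly* on the peak day, then exponential decline
  (default 2 %/day — the sources say only "slight decline", so a small round
  rate was fixed once). The endpoint anchoring is what makes noiseless
  productivity recovery exact rather than asymptotic: with K = 1.6 g/L and
  inoculum 0.1 g/L the true biomass productivity over days 0–8 is
  (1600 − 100)/8 = 187.5 mg/L/day, and `series_productivity()` recovers it
  to machine precision.
* **lipid content**: a sigmoid in time from a baseline to a plateau
  (nutrient-limitation-driven accumulation);
* **fucoxanthin content**: a Gaussian bump centred on its peak day (pigment
  rise through exponential phase, bleaching afterwards).

Default parameters are the study's printed laboratory outcomes (carrying
capacities 0.86/1.6 g/L, lipid plateaus 252.8/539.25 mg/g, fucoxanthin peaks
4.04/20.44 mg/g); they parameterize the emulation and are never themselves
claimed as computable results. Noise is **multiplicative log-normal**
(`x·exp(N(0, σ))`, default σ = 5 %): measured quantities are positive and
published SDs scale with means, which additive Gaussian noise would violate
at low concentrations. Two exact inverses close the loop: absorbance records
generated from a true fucoxanthin content round-trip through
`fucoxanthin_content()` to &lt; 1e-9, and simulated fatty-acid profiles hit a
target ADU exactly by linear mixing on the simplex (ADU is linear in
composition, so mixing a random Dirichlet draw with the extreme composition
concentrated on the least/most unsaturated acid solves the target in closed
form). Identified totals default to 95 %, emulating sub-100 % GC-MS tables.

Everything is seed-deterministic: the same config and seed regenerate
bit-identical data, and seeded calls restore the caller's RNG stream.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: nutrient-uptake mechanism (no Monod/Droop
dynamics), light attenuation and photoacclimation, OD-to-dry-weight optics,
correlated errors between channels measured on the same extract, and
day-to-day autocorrelation of measurement error. Recovery results on
synthetic data validate the analysis arithmetic, not the biology.

## 7. Problem sizes and numerical choices

The test suite uses deliberately small problem sizes — 1 000 fuzzed ADU
values for the affine identities, 50-draw fuzz loops for conservation and
round-trip properties, 200 seeded simulations for the two-treatment power
check and 500 for replicate-mean concentration — chosen as the smallest
sizes at which the checks are statistically meaningful; the full suite runs
in well under a minute of compute. Ties in the letter display are broken by
descending group mean; clique enumeration is exact, not heuristic, because
treatment counts in factorial cultivation designs are single-digit.
Comparisons against published 2-dp values use ±0.02 absolute tolerance
(input rounding); internal identities use 1e-9.

## 8. Known limitations

* The property correlations are single-predictor linear fits; they ignore
  chain-length effects that multi-descriptor models capture, and they are
  only as good as their calibration range (ADU roughly 0–3).
* The standalone published property panel is internally inconsistent at the
  hundredths digit (its KV, CN and density cells back-solve to slightly
  different ADUs than its IV/Cp/HHV cells); the package reproduces it cell
  by cell within the 2-dp input-rounding tolerance and exactly where the
  table is self-consistent.
* Cold-flow descriptors (SV/LCSF/CFPP) are literature forms, unverified
  against the reference analysis, and are flagged as such in every output.
* The statistics module implements fixed-effects one-way designs only — the
  design of the emulated study — not repeated-measures or mixed models.
```{r session}
sessionInfo()
```
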