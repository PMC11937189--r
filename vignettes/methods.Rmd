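---
title: "Methods: bucketing, OPLS-DA and NMR/GC-MS fusion in oplsFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bucketing, OPLS-DA and NMR/GC-MS fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oplsFusion)
```

This vignette is the package's own account of the science it implements:
the models, the conventions fixed where the underlying laboratory protocol
is silent, what the simulator emulates, and the limits of what a green
test establishes.

## 1. The bucketed NMR data matrix

A 1D ¹H-NMR spectrum enters as `(ppm, intensity)` pairs; non-uniform
sampling is supported because every integral in the package is the exact
trapezoidal integral of the linear interpolant. Preparation applies, in
order:

1. **Solvent referencing.** The axis is shifted uniformly so the
   maximum-intensity point inside a search window (default δ 3.25–3.35)
   lands on the solvent shift (default CH₃OH, δ 3.30). Argmax referencing
   is deliberate: it needs no lineshape model and is exact once the
   solvent line dominates its window.
2. **Total-integral normalization.** Intensities are scaled so the
   full-axis integral of |intensity| equals a constant (default 100).
   "Total integral mode" names a normalization family, not a constant; a
   constant-sum convention is the standard reading and the constant is
   irrelevant downstream because Pareto scaling and Pearson correlation
   are scale-free per column.
3. **Bucketing.** Bins are half-open `[edge, edge + width)` with edges at
   multiples of the width (default 0.04 ppm) from δ 0 to 10. A bucket's
   *value* is the integral over its bin; its *label* is the bin midpoint
   ("median") — the only reading of the median-label convention consistent
   with reference tables in which a triplet at δ 2.27 occupies buckets
   2.30 and 2.26.
4. **Water exclusion.** Every bin with *positive-measure* overlap with
   δ 4.60–5.00 is dropped: the ten bins labelled 4.62–4.98, leaving 240
   buckets. A closed-interval overlap rule would also drop the bin
   starting exactly at 5.00 and give 239; the printed lattice fixes the
   rule.

## 2. Multiplet projection onto the lattice

Reference assignments are communicated as multiplets (δ, pattern, *J*,
spectrometer MHz). The ppm interval a multiplet covers is its outer-line
coupling span converted at the spectrometer frequency, centred on δ:

| pattern | span (Hz) |
|---|---|
| s, brs | 0 |
| d | J₁ |
| t, brt | 2·J₁ |
| q | 3·J₁ |
| sext | 5·J₁ |
| dd | J₁ + J₂ |
| dt | J₁ + 2·J₂ |
| m (reported as a range) | the range itself |

The interval is closed; bins are half-open; an endpoint exactly on an edge
belongs to the higher bin (this reproduces the dt at δ 6.89 → buckets
6.94/6.90/6.86). Intrinsic linewidth is ignored by default (`extraHz`
adds a configurable half-width). Multiplets written "m" with a centre but
no range get span 0 — the only defensible choice without inventing a
width. The packaged reference table (`ginger_multiplets.tsv`) carries a
`span_rule` flag: rows whose printed bucket lists the span rule reproduces
exactly (32 rows, asserted in the tests) versus rows reflecting observed
shifts or linewidth in the real extract (e.g. the αr-curcumene methyl
singlet at δ 2.29 printed as buckets 2.34/2.30); no extra rule is guessed
for the latter.

## 3. GC-MS tables

Peak areas are divided by the sample's internal-standard area (ethyl
decanoate in the reference protocol); the operation is idempotent and
scale-free across injections. Identification support uses the *linear*
(temperature-programmed) retention index against a C9–C40 n-alkane
ladder, RI = 100·(n + (rt − rtₙ)/(rtₙ₊₁ − rtₙ)); no extrapolation
outside the ladder (out-of-range compounds are flagged, not dropped).
Compounds absent from a sample are stored as zero area with a missingness
flag — the aligned-matrix convention upstream tools produce.

## 4. Chemometrics

**Pareto scaling** mean-centres and divides by the square root of the
sample standard deviation (n−1 denominator), the usual compromise for
spectroscopic intensities; constant columns are centred, left undivided
and flagged. **PCA** is the thin SVD of the scaled matrix; explained
fractions are squared singular values over total variance, matching "PC
contribution" percentages from standard software.

**OPLS** is NIPALS-based. Per orthogonal component, a provisional PLS
component is fit, and its X-loading **p** is projected orthogonal to the
column space of X'Y (by QR); the result, normalized, is the orthogonal
weight. For a single response this is exactly the classical
w₀ = p − (w'p)w step; for multi-column Y it guarantees — by construction,
not approximately — that every orthogonal score has zero covariance with
every response column. Predictive components are then ordinary NIPALS PLS
on the filtered matrix, so a model with zero orthogonal components *is*
PLS (the test suite asserts equality with an independent PLS1 oracle at
1e-8). Convergence: 1e-10 on the weight change, 500 iterations maximum,
deterministic initialization from the largest-variance Y column. Sign
convention: each weight vector is flipped so its largest-magnitude entry
is positive; for discriminant models the predictive component is instead
oriented toward the positive class so S-plots always show the
processed-class markers on the positive side.

A note on a tempting intuition: a response exactly proportional to one X
column gives R²Y = 1 with a *single* predictive component only when that
column is orthogonal to the rest (disjoint bucket support); with
correlated columns the single PLS weight vector mixes them, and exactness
requires a full-rank predictive fit. The tests construct both worlds
explicitly.

**Cross-validation.** Q² = 1 − PRESS/SS with SS the total sum of squares
of the centred response. Folds are assigned by a seeded shuffle followed
by round-robin, stratified by class for discriminant models; X and Y are
re-centred per training fold. The default of 7 folds is the de-facto
standard of commercial chemometrics software; the protocol this package
follows is silent on the count, so it is an explicit config entry.

**OPLS-DA** encodes two classes as one centred 0/1 dummy (the second
factor level positive). Any monotone encoding yields the same scores up
to scale. Each class must have at least as many members as folds.

**Permutation test.** Labels are permuted `nPerm` times (at least 20;
200 conventional) and the model refit with identical settings. The R² and
Q² intercepts are ordinary least-squares lines of the refit R²Y and Q²
on |corr(y_perm, y)|, *including* the unpermuted model at correlation 1;
the model is valid if they fall below 0.3 and 0.05. Whether reported
single permutation R²/Q² values are intercepts or means is ambiguous in
parts of the literature; the intercept reading matches the cited validity
convention and is what this package computes.

**S-plot.** Per variable, p(cov) = cov(t, x) against
p(corr) = corr(t, x) for the first predictive score; extremes of |p(corr)|
are candidate markers. Zero-variance variables get p(corr) = 0 with a
flag rather than NaN.

## 5. Fusion heatmap and marker ranking

The fusion model regresses the IS-standardized compound block on the
bucket block, both Pareto scaled, default 1 + 2 + 0 components. The
heatmap is Pearson r across samples between each bucket and each
compound. Because the exact statistic behind "correlations obtained by
OPLS" is not fully specified in the source workflow, both readings ship,
labelled: `raw` (plain Pearson; the default) and `opls_filtered` (Pearson
after subtracting the model's Y-orthogonal X variation, X − Σ t₀p₀').
Per-compound ranking is by descending r with exact ties broken by
descending ppm, and reported buckets can be annotated with any reference
multiplet whose lattice projection contains them — the step that turns an
anonymous bucket into an assigned signal.

## 6. Quantification

Calibration is unweighted OLS of area on concentration (mg/mL) over at
least three points; R² and the calibrated range are retained, and areas
outside the range are flagged as extrapolated rather than rejected —
routine GC-FID practice. Content is
concentration × extraction volume (mL) / sample mass (g), reported in
mg/g; with the standard 10 mg / 1 mL ultrasound extraction a 0.0119 mg/mL
extract reads 1.19 mg/g. Replicates are summarized by mean and sd on the
content scale.

## 7. The simulated cohort — the stated world

`generateCohort()` draws, per sample, compound concentrations log-normal
around class means (arithmetic-mean parameterization, relative sd `cv`),
builds each bucket row as Σ concentration × protons-per-bucket (each
multiplet's protons split equally over its projected buckets) plus
additive Gaussian baseline noise clipped at zero, and each GC area as
concentration × response × multiplicative log-normal noise with a
constant IS area. Defaults, fixed once:

- 40 + 40 samples (echoing the 80-sample GR/PGR design), configurable
  down to 5 + 5 for fast tests;
- biological cv = 0.2 — typical batch-to-batch variation for crude-drug
  constituents; baseline sd = 1% of the median positive bucket signal;
  instrumental GC cv = 0.1 (smaller than biological, as observed in
  QC-bracketed runs);
- class means anchored to the reported contents where they exist:
  α-zingiberene 1.19 (GR) vs 0.85 (PGR) and αr-curcumene 0.65 vs 1.30
  mg/g — the processing-induced oxidation of zingiberene to curcumene;
  sugars and fatty acids class-neutral bulk constituents (50/30 and 5–8
  units); [6]-gingerol 4 → 3.2 and [6]-shogaol 1.5 → 2.1, modest shifts
  in the dehydration direction, chosen so that — as in the real data —
  the curcumene signals are the *dominant* positive-class markers while
  gingerol/shogaol contribute without overwhelming them;
- sugars carry no GC response (hexane-extract volatiles only), so the Y
  block holds 7 compounds.

With `emitSpectra = TRUE` the generator also renders each sample as
narrow Gaussian lines (sd 0.004 ppm) at the planted bucket centres on a
0.0025-ppm axis, so the full bucketing pipeline can be exercised and
shown to round-trip the planted projection.

What the simulator does **not** emulate: chemical-shift drift between
samples, linewidth and lineshape variation, baseline roll, spectral
overlap beyond the bucket lattice, retention-time drift, or detector
saturation. A green recovery test therefore establishes that the
*statistics* (scaling, OPLS-DA, permutation machinery, correlation
ranking) behave as designed on data with the assumed structure — not that
the workflow is robust to instrumental artifacts it never sees.

The cohort-dependent headline figures of the original 80-sample study
(R²Y = 0.886, Q² = 0.820, PC contributions, fusion R²Y/Q², absolute
contents) depend on the physical samples and are not reproduced as
machine targets; the test suite instead checks exact lattice arithmetic,
oracle equivalence of every model component, and planted-marker recovery
across seeds.

## 8. Degenerate inputs and error policy

Empty solvent windows, non-positive total integrals, spectra disjoint
from the grid, patterns lacking coupling constants, rank-deficient X
beyond the requested components, single-class label vectors, zero IS
areas (named per sample) and zero calibration slopes are hard errors with
specific messages; zero-variance columns in correlations/S-plots and
out-of-ladder retention times are flagged results, not errors. Fold
assignment, permutations and the generator restore the caller's RNG
state, so seeded pipelines are reproducible and side-effect free.

## 9. Known limitations

Y-orthogonal components (the third count in "a + b + c") are rejected
rather than implemented — the reference workflow uses 0 throughout. No
FID processing, peak picking, 2D-NMR parsing, GC deconvolution or library
matching: inputs are processed spectra and aligned peak tables. Only the
linear retention index is provided (isothermal/Kovats logarithmic form is
out of scope), and multi-class discriminant analysis and VIP scores are
deliberately absent.
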