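---
title: "Plate-reader UV-Vis chemometrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plate-reader UV-Vis chemometrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platespec)
```

This vignette is the package's account of the science it implements: the
measurement model, the pretreatments, the classifiers, the synthetic data the
tests rely on, and the places where the design was genuinely open and a
choice had to be made.

## The measurement model

A microtiter plate reader records optical density (OD) through a vertical
light path: the pathlength is the fill height of the oil column in the well,

$$L(w) \;=\; \frac{w/1000}{\rho \,\pi (d/2)^2}\ \text{cm},$$

for an aliquot of weight $w$ mg, oil density $\rho$ g/cm³ and well diameter
$d$ cm, assuming a flat meniscus (no curvature correction is applied — the
meniscus of neat oil in a 0.86 cm polystyrene well is treated as flat). With
the defaults ($d = 0.86$, $\rho = 0.9113$, a 10 mm reference cuvette),
100/150/200/300 mg aliquots give 1.9/2.8/3.8/5.7 mm; `estimate_pathlength()`
is exactly linear in weight and `pathlength_ratio()` returns the
cuvette-to-well ratio unrounded. Under Beer–Lambert behaviour the mean OD at
a fixed wavelength is therefore affine in aliquot weight, which
`fit_od_weight()` checks by ordinary least squares at a configurable
reference wavelength (default 415 nm, a strong carotenoid absorbance of
olive oil).

Two detector artifacts shape the raw data. First, absorbance of neat oil
below roughly 308 nm exceeds the instrument's dynamic range: readings are
pinned at the maximum indication (OD 4). `cap_overflow()` replaces every
overflow marker, non-finite value and super-cap value by exactly the cap and
reports how many cells it touched; `trim_band()` then removes the saturated
region, taking the 230–1000 nm acquisition grid at 1 nm to 693 retained
variables (308–1000 nm). Capping is applied to the raw data before any other
processing, because saturation is a property of the acquisition, not of the
analysis.

## Pretreatments

**MSC.** Each spectrum is modelled as an affine distortion of an ideal
spectrum, $A_i = m_i \bar A + b_i$, with the set mean $\bar A$ standing in
for the unavailable ideal. $(m_i, b_i)$ are estimated per sample by OLS over
wavelengths — solved via a QR factorisation with a rank check rather than
the normal equations, so a degenerate (constant) reference fails loudly
instead of silently producing garbage — and the corrected spectrum is
$(A_i - b_i)/m_i$. Samples whose fitted slope is below $10^{-12}$ in
magnitude are reported by name as non-correctable. `apply_msc()` always
re-estimates the coefficients against the *model's stored reference*, so a
model fitted on training data applies to held-out spectra without touching
them during fitting.

**Derivatives.** The first-level derivative is the adjacent finite
difference $y_i = x_{i+1} - x_i$ on the uniform grid; it removes any
additive constant. The second level is the first difference applied twice
and removes a linear background. The output grid is labelled by the left
wavelength of each difference — the convention is arbitrary (any consistent
labelling leaves a classifier unchanged) but keeping the integer grid makes
round trips through CSV exact. MSC followed by the first derivative
(`msc_der1()`) is the default pretreatment of the pipeline.

**Savitzky–Golay and EMSC.** Both are provided as functioning alternatives:
SG smoothing (delegated to `signal::sgolayfilt`, which is exact on
polynomials up to the fit degree including at the edges; window 11 points,
degree 2 by default — a common chemometrics choice) and EMSC, which extends
the MSC design matrix with wavelength polynomials up to degree 2 by default,
with the wavelength axis rescaled to $[-1, 1]$ for conditioning. EMSC at
degree 0 reduces elementwise to MSC, which the tests assert at $10^{-10}$.
No accuracy claim is attached to either: they exist so that pretreatment
comparisons can be run, not because they improve the default pipeline.

## PCA and the component-count rule

PCA is computed by SVD of the column-centered matrix; loadings are unit-norm,
scores are the centered projections, and the explained-variance ratio is the
squared singular value over the total. The SVD sign ambiguity is pinned by
making the largest-magnitude element of each loading positive, so score
plots are reproducible run to run.

Choosing how many components to interpret uses two criteria: a component
counts as informative if it explains at least `var_floor` (default 1%) of
the variance *or* its loading is structured rather than noise-like. The
"noise-like" judgement — visually obvious on a loadings plot — is
operationalised as $1 - R^2$ of the loading against its own SG-smoothed
version (window 11, degree 2): a smooth band-shaped loading scores near 0, a
white-noise loading near 1, and the threshold `noise_ceiling` defaults
to 0.3. A constant loading is a guarded 0/0 and returns 0 by convention.
The selected count is the largest $k$ such that every component up to $k$
is informative, with a minimum of 1. With variance ratios like
96%/2.5%/0.9%/0.2% and noisy third and fourth loadings the rule selects 2.

## PLS-DA and cross-validation

Class labels are one-hot encoded (0/1, first-appearance column order) and
both blocks column-centered; no variance scaling is applied, matching common
chemometrics practice for spectra whose variables share units. Components
are extracted by NIPALS: iterate $w = X'u/\lVert X'u\rVert$, $t = Xw$,
$q = Y't/(t't)$, $u = Yq$ until the score vector changes by less than
$10^{-10}$ (relative; at most 500 iterations, with a warning naming the
component on non-convergence), then deflate both blocks by the rank-one
score contribution. The coefficient matrix is $B = W(P'W)^{-1}Q'$;
components are nested, so one fit at the largest latent-variable (LV) count
serves every smaller count. If the $Y$ residual is numerically exhausted
before the requested count, extraction stops early — the remaining
components carry nothing. Predicted class is the argmax of the continuous
indicator predictions, ties broken deterministically toward the earlier
class in the encoding order. At maximal LVs on full-rank data PLS-DA
reproduces pseudo-inverse least squares, which the tests assert at
$10^{-6}$ against an independent `MASS::ginv` oracle; the implementation is
also cross-checked against `mixOmics::plsda` (weights and predictions) on a
toy problem.

Cross-validation is stratified 5-fold, repeated 10 times. One master seed
spawns one child seed per repeat; within each class, units are shuffled and
fold labels dealt cyclically, keeping per-fold class counts within ±1.
The grouping level defaults to `spectrum` (every spectrum assigned
independently); `sample` grouping keeps the replicates of one oil together
and is the right choice when replicate leakage matters — with 4 brands per
class it caps the fold count at 4. Statistics-bearing pretreatment steps
(the MSC/EMSC reference, centering) are fitted on the training rows of each
fold only and applied to the held-out rows (`msc_scope = "fold"`); a
`global` scope reproduces the leakage-prone reading. Accuracy is pooled
over folds within a repeat, then averaged over repeats — a convention that
must be fixed for reproducibility since only one number is reported per LV
count. `select_n_lv()` picks the smallest LV count within `tolerance`
(default 0.01) of the best accuracy, preferring parsimony because large LV
counts overfit.

One subtlety the test suite encodes: under label permutation, per-repeat
accuracies share the same permuted labels and are strongly correlated, so a
standard error across repeats badly understates the spread of the null. The
permutation null is therefore assessed as a mean over independent
permutations with the standard error taken across permutations; so
estimated, it is consistent with chance (1/3 for three balanced classes).

## The synthetic generator

The generator emulates the statistical structure the rest of the package
assumes, with known ground truth. Per brand, pigment concentrations are
drawn around class means (truncated-positive normal, 8% relative
between-brand SD); the extinction spectrum per mm of pathlength is the sum
of Gaussian pigment bands — tocopherol at 325 nm, the broad
carotenoid/pheophytin composite at 420 nm (30 nm SD), α/β/γ-carotene at
447/451/462 nm, chlorophyll at 670 nm (12 nm SD each, which keeps the
carotene shoulders resolvable) — plus a steep exponential UV edge
(amplitude 700 per mm at 230 nm, 12 nm decay) that drives the sub-308 nm
saturation. The OD of a well is the extinction times `estimate_pathlength()`
of the aliquot, distorted per replicate by $m_i \sim N(1, 0.05)$ (truncated
positive) and $b_i \sim N(0, 0.01)$, plus a fixed polystyrene-well
background (0.05 OD at 230 nm, 80 nm decay — absent from the quartz-cuvette
benchtop condition), plus iid point noise ($\sigma = 0.002$ OD, the
photometric-repeatability scale of a monochromator plate reader), then
capped at OD 4. Everything is bitwise reproducible under the seed and the
global RNG state is restored afterwards.

The default design is 3 regions × 4 brands × 5 replicates = 60 spectra at
200 mg. The regions differ in tocopherol level, carotene balance and
chlorophyll:carotenoid ratio. That they differ in several *ratio*
dimensions is deliberate: MSC is a normalization, so two classes whose mean
spectra are scalar multiples of one another collapse onto each other after
correction regardless of their amplitudes — an early single-ratio design
made two regions nearly indistinguishable for exactly that reason. Effect
sizes are free parameters of the generator (no quantitative between-region
chemistry is available to copy), chosen once so that class structure
dominates within-class dispersion: the mean silhouette of brand-mean spectra
in MSC-Der1 space is positive, and under the default conditions the
repeated-CV accuracy at 5 LVs exceeds 0.95 across generator seeds 0–4, the
regime in which this kind of workflow is reported to succeed on real oils.

Vegetable oils (two corn, four sunflower, two soy by default) have nearly
absent chlorophyll, paler and differently balanced carotenoid bands, and a
2.5–3× stronger UV edge, so some of their spectra stay saturated above
308 nm — exercising in-band overflow capping — and their first-two-PC scores
separate linearly from the olive cluster.

The weight series draws each brand's true spectrum once and measures it at
100/150/200/300 mg and in a benchtop-like 10 mm condition (triplicate,
independent noise). Instrument agreement is assessed as the Pearson
correlation between condition-mean spectra over 330–1000 nm: at 10 mm the
cuvette condition is itself saturated up to roughly 320 nm, and a
detector-pinned flat region measures the detector, not the spectra, so the
comparison is restricted to wavelengths where both instruments are within
dynamic range. On that band the correlation with the benchtop condition
increases deterministically with aliquot weight, because the fixed well
background is diluted by a growing signal — the mechanism behind the
observation that larger fills agree better with the cuvette.

What the generator does **not** emulate: stray light and detector
nonlinearity near the cap, wavelength-dependent noise, meniscus curvature,
instrument-specific baseline drift beyond the constant per-replicate offset,
and any physically calibrated extinction coefficients. Passing tests on
synthetic data therefore demonstrate the correctness and statistical sanity
of the workflow, not field performance on real oils; real-data accuracies
can only be matched qualitatively.

## Numerical choices and degenerate inputs

* All per-sample OLS fits (MSC, EMSC) go through one QR factorisation of the
  design, with explicit rank checks; rank-deficient designs and
  zero-variance references raise errors naming the problem.
* NIPALS tolerance $10^{-10}$ on the relative change of the score vector,
  500 iterations — conservative for ~700-variable problems.
* `sg_smooth()` requires an odd window larger than the polynomial degree and
  no longer than the grid; window 1 with degree 0 is the identity.
* Overflow markers default to `OVER`, `OVRFLW`, the empty string and `inf`;
  they are configurable because instruments disagree, and are ingested as
  `Inf` so that nothing silently becomes a plausible number before capping.
* An empty trim window, duplicate long-format keys, metadata joins that miss
  a sample, non-uniform grids and header-only files are all hard errors at
  ingestion; after ingestion the pipeline operates on total functions.
* `run_pipeline()` removes its own partial outputs when a stage fails, and
  its manifest (config echo, seed, per-stage shapes) makes a run
  reproducible byte for byte given the same inputs.

## Problem sizes

The test suite and the reproduction script run the full default design
(60 × 693 spectra, 5-fold × 10-repeat CV over LV grids up to 10, five
generator seeds for the recovery check) — a few seconds per CV run — plus
small constructed fixtures for the exactness oracles.

## Known limitations

The component-count and LV-selection rules operationalise judgements that
are partly visual in practice; their thresholds are configurable rather than
canonical. The CLI is a thin wrapper, not a workflow manager.
`equivalent_weight()` is plain inversion of the fitted OD–weight line; note
that it answers a different question than pathlength equality (the aliquot
filling a well to the 10 mm cuvette height is ≈529 mg with the default
geometry), so "weight giving a cuvette-like spectrum" depends on which
criterion is meant.
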