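---
title: "Detecting fish scaling rates from Vis-NIR spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fish scaling rates from Vis-NIR spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalespec)
```

## The problem

Mechanical descaling of carp is monitored by the *scaling rate*: the
percentage of a body region's surface area from which scales have been
removed, `P = 100 * P1 / P2` with `P1` the descaled pixel area and `P2`
the region's pixel area. Manual measurement is subjective and slow;
visible/near-infrared hyperspectral imaging offers a nondestructive
alternative because scale and skin reflect light differently: the
inorganic fibre structure of scales scatters strongly, while pigmented,
moist skin absorbs, so mean reflectance of a region decreases
monotonically as more skin is exposed.

`scalespec` implements the full calibration workflow on that physical
picture: reflectance correction of raw hypercubes, region-of-interest
(ROI) extraction, four spectral pretreatments, three
characteristic-wavelength (CW) selectors, partial least squares
regression (PLSR), and the evaluation matrix used to pick an operational
model per body region (back, belly, tail). Because no public dataset of
descaled-fish hypercubes exists, the package also ships a synthetic
generator that reproduces the statistical structure the workflow
assumes, so every stage is testable end to end.

## The synthetic generator

A sample spectrum is modelled as linear areal mixing of two endmembers
plus measurement artifacts:

```
x(lambda) = g * [ (1 - P/100) * scale(lambda) + (P/100) * skin(lambda) ] * 100
            + o + e(lambda)
```

* `scale`, `skin` — smooth reflectance endmembers (fractions in 0–1) on
  the shared wavelength axis, with `scale > skin` strictly at every band.
  Both carry Gaussian absorption dips near 420 nm (porphyrin Soret band,
  sharp), at ~525 and ~575 nm (myoglobin bands — the "several peaks in
  500–600 nm" seen in fish surface spectra), and near 960 nm (water
  overtone). The dips are substantially deeper in skin, where the
  pigments, myoglobin and water reside; the scale dips are 20–35% of the
  skin dips. This matters: it makes the scale−skin difference
  wavelength-structured rather than a flat offset, which is what lets
  derivative- and scatter-corrected pretreatments retain scaling-rate
  information — published derivative-based 8-band models reach
  prediction R² near 95%, which is only possible when the difference
  spectrum has sharp features.
* `g ~ N(1, 0.1)` — multiplicative scatter gain per sample (what MSC and
  SNV remove).
* `o ~ N(0, 2)` percent reflectance — additive baseline offset (what
  differentiation removes).
* `e ~ N(0, 0.1)` percent reflectance per band — residual white noise
  (what Savitzky–Golay smoothing suppresses). The default is small
  because each simulated spectrum represents a ROI mean over the
  thousands of pixels in a 2 × 2 cm block, measured in triplicate:
  spatial and replicate averaging suppresses per-pixel sensor noise by
  orders of magnitude, leaving sample-to-sample scatter and baseline
  shifts as the dominant artifacts.

Scaling rates are drawn uniformly on [0, 100]% (the study design spans
the full range; no distribution beyond the range is documented, and the
uniform choice exercises the calibration evenly). One hundred samples
per region mirror the reference design. Distinct body regions are
emulated by different endmember seeds: the dip geometry and base level
jitter within physiologically sensible bounds.

The default wavelength axis has 352 uniformly spaced analysis bands from
400.6 to 1024.7 nm (spacing ≈ 1.778 nm), extended 8 bands downward to
~386 nm so the trimming step — discarding the noisy, overlapping bands
below 400 nm — has something to do. `trim_to_analysis_range()` keeps
exactly 352 bands on this axis.

The cube generator (`simulate_cube()`) wraps the same mixing model in a
small scene: per-pixel endmember assignment from a ground-truth scale
mask hitting a requested coverage fraction to within one pixel,
per-pixel artifacts, and white/dark reference frames synthesised so that
reflectance correction recovers the simulated reflectance exactly. The
implied scaling rate of a scene with scale coverage `c` is
`P = 100 * (1 - c)`.

What the generator does **not** emulate: spatial texture and
illumination gradients within a scene, wavelength-correlated (pink)
noise, specular glints, partial scale fragments, or any nonlinearity in
the mixing. Tests passing on this generator therefore demonstrate
correctness of the algorithms under the stated model, not performance on
real fish.

## Preprocessing

All four pretreatments operate per sample (row-wise); MSC is the one
dataset-level fit.

* **SG** — Savitzky–Golay least-squares polynomial smoothing, order 3,
  window 7 bands (the standard setting for ~1.8 nm sampling). Edges are
  handled by explicit polynomial fits over the first and last window
  rather than mirror padding: polynomial-fit edges reproduce any cubic
  input exactly at every band, whereas mirror padding biases the edge
  curvature.
* **FD** — first derivative with respect to wavelength as the central
  difference `(R[W+1] - R[W-1]) / (lambda[W+1] - lambda[W-1])`, exact
  for locally quadratic spectra; one-sided differences at the two
  boundary bands preserve the band count.
* **MSC** — each spectrum is regressed (OLS) on the dataset-mean
  reference; the fitted affine distortion is inverted. `msc_apply()`
  carries a calibration-set reference onto new spectra.
* **SNV** — per-spectrum centring and scaling to unit sample standard
  deviation (denominator `m - 1`).

In the model matrix the pretreatment is applied to the full region
dataset before splitting, matching the convention that the MSC reference
is the mean of the whole regional data set.

## Wavelength selection

* **SPA** (`spa_select()`) grows, from every candidate start band, a
  chain in which each new band maximises the projection norm orthogonal
  to the bands already chosen — minimum collinearity by construction.
  Chain prefixes of size 3–10 are scored by leave-one-out RMSE of a
  multiple linear regression (the standard SPA companion; a PLSR scorer
  is available), and the smallest subset within 1% of the minimum RMSE
  wins. Being a greedy heuristic, SPA explores only the ~b² chain
  prefixes, not all 2^b − 1 subsets; it is not (and cannot be) an
  optimal best-subset search, a point the test suite documents
  explicitly.
* **RC** (`rc_select()`) fits a full-spectrum PLSR and keeps the
  `n_keep = 8` local extrema of the regression-coefficient vector with
  the largest absolute values — published subsets of this kind have 4–9
  bands.
* **2D-COS** (`synchronous_spectrum()` + `autopeak_select()`) treats the
  scaling rate as the external perturbation, orders samples by it, forms
  dynamic spectra as deviations from the perturbation-mean spectrum
  (the standard reference choice), and computes the synchronous
  correlation matrix `t(D) D / (m - 1)` — symmetric and positive
  semidefinite by construction. Diagonal auto-peaks with prominence
  above 5% of the diagonal maximum (enough to keep weak but real
  auto-peaks while rejecting ripple) become CWs, capped at 8, tallest
  first. Boundary bands may qualify: perturbation-sensitive bands do sit
  at the edge of the analysis range in this application.

## Regression and evaluation

`fit_plsr()` is a single-response NIPALS implementation: successive
covariance-direction weights on deflated, centred data, with mutually
orthogonal scores; weights, loadings and response loadings collapse into
one coefficient vector plus intercept. Predictors are centred but not
variance-scaled — the pretreatments already condition the spectra. At
full rank the coefficients coincide with ordinary least squares, which
the tests verify against an explicit pseudo-inverse.

The component count is chosen by 10-fold cross-validation with the
one-standard-error parsimony rule (smallest count whose CV RMSE is
within one SE of the minimum), capped at `min(20, rank)`. Folds are
assigned deterministically across response ranks so each fold spans the
rate range. The reference study never reports its per-model component
counts, so no attempt is made to reproduce them.

`split_dataset()` defaults to a deterministic rank split: samples are
sorted by response and prediction samples taken at evenly spaced ranks
(60/40 by default), so both sets cover the rate range; a seeded random
strategy is available.

`compute_metrics()` reports R² (percent), RMSE (percent scaling rate),
the standard deviation of the *predicted* values on the fractional
scale (the convention of published evaluation tables, where 0.18 means
18%), its standard error, and — for the prediction set — the relative
percent deviation `RPD = 100 * SD_pred / RMSEP`. That fractional-scale
convention is verified against the shipped reference table, where
recomputing RPD from the printed SD and RMSEP pairs reproduces the
printed RPD cells to two decimals wherever the printed rounding of SD
permits. Grading uses the conventional closed-boundary thresholds:
prediction R² below 82% inaccurate, 82–90% good, above 90% excellent;
RPD below 1.5 unusable, 1.5–2 usable, above 2 excellent.

`run_model_matrix()` evaluates all 4 pretreatments × {FW, SPA, RC,
2D-COS} = 16 models per region and `select_optimal_model()` ranks the
CW rows by prediction R², then by the stability criterion
`|RMSEC − RMSEP|`, then by RPD. That tie-break order mirrors how such
models are argued for in the applied literature (accuracy first,
stability as the stated discriminator between near-ties), and is stated
explicitly here because it is rarely formalised.

## Numerical choices and degenerate inputs

* Reflectance correction refuses any band where the white reference does
  not exceed the dark frame, and names the offending band.
* ROI indexing is 0-based and half-open, so ROI sizes are differences of
  bounds and adjacent ROIs tile exactly.
* MSC refuses a constant reference; SNV refuses zero-variance spectra;
  PLSR reports the achievable component count on rank-deficient input.
* SPA drops chain branches whose projected norms fall below
  `1e-10 * max band norm` (exact collinearity), so a duplicated band is
  never selected together with its twin.
* All generator randomness flows through one integer seed per physics
  object; identical seeds give bit-identical datasets, cubes and splits.
* Wavelength axes must be uniformly spaced within 1e-6 nm; a single-band
  axis is degenerate-valid so that trimming to a half-spacing window can
  return exactly one band.

The scaling-rate responses are stored in percent by default; because
some published summary statistics quote rate standard deviations on the
fractional scale (values like 0.22 for rates spanning 0–100%),
`simulate_dataset(rate_scale = "fraction")` exposes the other
convention rather than guessing which one a downstream consumer wants.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline on
100-sample regional datasets over the 360-band default axis (352 after
trimming), with the 60/40 rank split — the reference study design. The
SPA-versus-exhaustive comparison uses 200 random instances of 3–6 bands
and 15 samples, where exhaustive search over all subsets is feasible;
the PLSR-versus-OLS check uses 50 random full-rank instances. These
sizes were chosen so each property is exercised at the scale where its
oracle is exact.

## Known limitations

* The generator's linear mixing ignores multiple scattering between
  scale and skin patches; real ROI spectra may mix nonlinearly at patch
  boundaries.
* SPA's greedy chains can miss the globally RMSE-optimal subset (see
  above); this is inherent to the algorithm, not a defect of the
  implementation.
* The evaluation matrix refits the wavelength selectors on the
  calibration set of each pretreatment independently; no attempt is made
  to stabilise the selected subsets across pretreatments or seeds.
* Published headline R²/RMSE values for real carp cannot be reproduced
  here because the underlying spectra were never deposited; the package
  validates the arithmetic identities those tables imply and the
  behaviour of the workflow under its own stated data model.
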