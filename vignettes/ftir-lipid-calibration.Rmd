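---
title: "Monitoring lipogenesis by FTIR: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring lipogenesis by FTIR: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirlipids)
```

This vignette is the package's account of the science behind its
functions: the preprocessing model, the calibration model, the synthetic
experiment generator, and the places where a genuine design choice had to
be made.

## The measurement model

A mid-infrared absorbance spectrum of dried biomass is, to a good
approximation, a Beer–Lambert mixture: each biochemical constituent
contributes bands proportional to its amount in the beam, and the whole
spectrum is wrapped in measurement artifacts — an additive offset, a
smooth baseline, and a multiplicative factor from the amount of material
deposited in the well. Preprocessing exists to strip the artifacts while
keeping the composition signal:

1. **Technical replicate averaging** (`average_technical_replicates()`)
   suppresses uncorrelated instrument noise by the usual √n factor.
2. **Savitzky–Golay second differentiation** (`sg_derivative()`, window 9
   points, polynomial degree 2) removes additive and linear baseline
   components exactly and sharpens overlapping bands. With the default
   spacing-aware scaling the output is in absorbance·cm²; a switch
   (`sg_scale = FALSE`) reproduces the unscaled convention of vendor
   software. The filter is exact on polynomials up to the fit degree,
   which the tests exploit as an oracle.
3. **EMSC** (`emsc()`) fits each spectrum as
   `z = a·1 + c·p₁ + d·p₂ + b·r` against a reference spectrum `r` and
   divides out `b`. The polynomial basis uses the wavenumber axis mapped
   affinely to [−1, 1]: raw wavenumbers up to 3100 squared would make the
   normal equations needlessly ill-conditioned, and the coefficients are
   reported in the scaled basis. With `poly_order = 0` the model is
   classic MSC.

The correction runs on the combined 3100–2800 + 1800–500 cm⁻¹ range as a
single least-squares problem, not per region — the two regions carry the
fungal fingerprint, and a joint fit uses one consistent scatter model for
both.

### Order of operations

Differentiation happens before region selection, and the half-window of
points where the SG window does not fit is trimmed rather than filled by
edge polynomials. Trimming costs 4 grid points per end of each region but
guarantees that no edge-fitting artifact enters the EMSC design matrix.
Whether the original analysis restricted the range before or after
differentiation is not documented; the trim-then-select order is this
package's choice and is visible in the output grid (e.g. the instrument
grid 4000→500 cm⁻¹ at 6 cm⁻¹ spacing, 584 points, becomes 264 points on
the combined region after trimming).

## The calibration model

`ftir_calibration()` regresses GC-derived fatty-acid parameters (Y) on the
preprocessed spectra (X) with mean-centered NIPALS PLS. Key choices:

* **PLS1, one model per response.** Different responses genuinely need
  different complexity (a total-lipid model saturates after one or two
  components; unsaturation needs more), and reporting per-response factor
  counts only makes sense with separate models. `pls_fit()` also accepts a
  response matrix (PLS2) for users who want one joint model.
* **No variance scaling of X.** All spectral channels share a unit;
  autoscaling would inflate noise-only channels.
* **Leave-one-day-out cross-validation** (`day_segmented_cv()`). Samples
  from the same cultivation day are strongly dependent — replicates of the
  same cultures — so random CV would leak and flatter the model. All
  spectra of one day are held out together.
* **Per-fold EMSC references.** The EMSC reference is the mean of the
  *training* spectra in each fold, and the held-out day is corrected
  against it. Correcting everything once against the global mean lets the
  held-out day influence its own preprocessing; the effect is small but
  the leak-free variant is the defensible default (`emsc_refit = FALSE`
  reproduces the simpler practice). A property test garbles the held-out
  day's responses and checks its predictions do not move.
* **Component choice: one-standard-error rule.** The stopping rule
  "smallest number of components whose RMSE is insignificantly higher than
  the minimum" is operationalized as: take the RMSE-minimising count k\*,
  and return the smallest k ≤ k\* with RMSE(k) ≤ RMSE(k\*) + SE(k\*),
  where SE is the between-segment standard error of the segment RMSEs.
  No significance test is named in the chemometric convention this
  follows; the 1-SE rule is the standard parsimony heuristic, and
  `select_components()` is exposed separately so another threshold can be
  substituted.
* **Replicate mapping.** GC reference values are per condition-day
  (pooled biomass), so one GC row serves as the Y value for all three
  biological replicate spectra of that condition-day. An exclusion table
  (`exclude`) drops condition-days — e.g. early-growth samples whose
  biomass composition is not yet representative — and the join refuses
  silently unmatched samples.

The report per response — Range, Mean, SD, cross-validated R² (squared
Pearson correlation of CV predictions with the reference), RMSECV, and
RPD_CV = SD/RMSECV — follows the conventional calibration-table layout.
The identity RPD·RMSECV = SD holds to machine precision before display
rounding (SD/RMSECV/RPD print at one decimal, R² at two, small-magnitude
responses like the unsaturation index keep three significant digits).

## Fatty-acid arithmetic

`quantify_fames()` implements internal-standard quantification:
mᵢ = Aᵢ/A_IS · RRFᵢ · m_IS, composition as % of total FAME mass, and
total lipid as total FAME mass over dry biomass. "Total lipid" is thus
fatty-acid-based lipid content; no correction from FAME mass to
triacylglycerol mass is applied, because the direct-transesterification
protocol being modelled measures exactly the FAME-accessible pool.

The unsaturation index weights each acid by its double-bond count
(monoenes ×1, dienes ×2, trienes ×3, saturates 0) and divides by 100.
The implementation uses the catalogue's `n_double_bonds` directly, so a
tetraenoic acid (e.g. arachidonic) would count ×4 — the natural extension
of the formula, which matters only for organisms outside the built-in
catalogue's trienoic scope.

## What the generator emulates — and what it does not

`simulate_experiment()` draws the full study design: 3 species (two
γ-linolenic producers, one α-linolenic producer) × 2 temperatures ×
12 days × 3 biological × 3 technical replicates = 648 raw spectra,
216 biological samples, 72 GC condition-days. Its defaults are the
conditions the emulated study reports, fixed once:

* **Lipid kinetics**: logistic per condition, start 8% of CDW, plateaus
  26–37%, onset days 2.5–3.5. These reproduce the published total-lipid
  distribution (range ≈ 8–37%, mean ≈ 27, SD ≈ 8).
* **Composition kinetics**: PUFA-rich start vectors shifting to MUFA-rich
  stationary vectors through a logistic centered on day 4 — composition is
  stable during growth, moves rapidly after the growth→stationary
  transition, and stabilizes, with cooler cultivation retaining more
  triene. Emitted unsaturation-index mean ≈ 1.12, SD ≈ 0.15.
* **Band physics**: components are Gaussian band sums (Gaussians because
  their second derivatives have closed forms, which keeps the SG stage
  analytically testable). Amplitudes follow functional-group densities:
  the olefinic =C–H band scales with the unsaturation index and its
  *position* moves linearly through the anchor points (UI 0.93,
  3006 cm⁻¹)–(UI 1.43, 3012 cm⁻¹); CH₂ bands scale with methylenes per
  chain (two fewer per cis bond); a bis-allylic CH band at 2940 cm⁻¹
  scales with polyunsaturation. Only the direction and the two anchors of
  the position–unsaturation link are established empirically; the linear
  form between them is a modelling choice with a configurable slope.
* **Noise model**: per-technical-replicate multiplicative scatter
  b ∈ [0.7, 1.3], offset and polynomial baseline terms, and 1 mAU additive
  white noise (the canonical figure for this instrument class). Under
  these defaults the mean technical-replicate Pearson correlation of the
  preprocessed spectra is ≈ 0.9998 — the same order as the reproducibility
  the emulated platform reports. Condition-day kinetic wobble
  (`day_jitter`, `lipid_day_cv`) is *shared* between the GC table and the
  spectra of that condition-day: real cultivations deviate from their mean
  kinetics, and that deviation is signal, not noise. Biological replicate
  jitter is two orders below the 12-day variation, matching the platform's
  stated replicate quality.
* **Glucose**: decreasing logistics per condition (the slow cold-grown
  culture keeps half its glucose), replicate SD 1.1 g/L, floored at zero.

What it deliberately does **not** emulate: Voigt/Lorentzian line shapes,
water-vapour and CO₂ interference, Mie-type scattering distortions,
detector nonlinearity, wavenumber miscalibration, pellet-morphology
effects, and any mechanistic fermentation model (no Monod kinetics or
oxygen transfer). Passing the recovery tests therefore shows the pipeline
is correct and leak-free under honest Beer–Lambert conditions with
realistic artifact levels — it does not certify performance on real
spectra, whose residual structure is richer.

The full factorial design emits 216 biological samples; the emulated
study's deposited tables hold 210, and which 6 design cells are missing is
not documented, so an explicit `drop` argument removes caller-chosen
condition-days when the incomplete design matters (the tests drop two
cells to reproduce the 630-spectra / 210-average accounting).

## Numerical choices and degenerate inputs

* EMSC declares a sample degenerate when |b| < 1e-8 (a spectrum with no
  reference contribution cannot be divided by its scale) and refuses
  rank-deficient designs (e.g. a reference that is itself a polynomial
  baseline).
* NIPALS has no random initialisation: the start vector is the
  largest-variance response column, so fits are bit-reproducible. If the
  predictor residual runs out of covariance before the requested component
  count, the achieved count is kept; a response orthogonal to X yields the
  null model that predicts the mean.
* `select_components()` breaks ties toward fewer components and never
  exceeds the argmin.
* Peak positions are refined by a three-point parabola; an extremum on the
  window boundary returns the grid value with a warning rather than an
  extrapolated vertex.
* Grids are stored descending (4000→500 cm⁻¹, spectrometer convention);
  region bounds are inclusive because the field writes closed ranges
  ("3100–2800 cm⁻¹"); mixed grids across files are rejected rather than
  silently resampled.
* The composition-sum tolerance on ingest is ±0.5 percentage points
  (published tables round minor acids); larger deviations warn and can be
  renormalized explicitly.

## Problem sizes

The test-suite and the acceptance script run the full factorial design
(648 spectra × 584 grid points, 264 predictors after preprocessing, 12 CV
segments × 25 component counts), which completes in a few seconds per
calibration; the property tests use small planted fixtures (tens of
samples) where closed-form oracles exist.

## Known limitations

* The calibration is linear; ratio-type responses (unsaturation index,
  composition percentages) are only locally linear in the spectra, so
  accuracy depends on the calibration population resembling the prediction
  population — as with any PLS calibration, extrapolation beyond the
  trained lipid-content range degrades gracefully but measurably.
* The replicate-correlation statistic is computed on whatever spectra the
  caller passes (raw or preprocessed) and over a configurable region;
  published single-number correlations rarely document those choices, so
  exact numerical comparison is inherently loose.
* JCAMP-DX support covers the plain AFFN `(X++(Y..Y))` dialect only; no
  vendor binary formats.
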