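---
title: "Generic Raman calibration models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generic Raman calibration models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanpls)
```

## The problem

In-line Raman spectroscopy is a standard tool for monitoring metabolite
concentrations (glucose, lactate, glutamine, glutamate) in CHO cell
cultivations. The usual workflow calibrates a partial least squares (PLS)
regression linking preprocessed spectra to off-line reference concentrations.
Such calibrations are notoriously instrument- and process-specific: moving a
model to another spectrometer or site normally requires full recalibration.

A *generic* model attacks this by pooling calibration data from many sites,
instruments, batches and process conditions, so the instrument-to-instrument
and process-to-process variance is *inside* the calibration rather than a
violation of it. `ramanpls` implements that workflow end to end —
wavenumber standardization, derivative/SNV preprocessing, NIPALS PLS1 with
grouped cross-validation, and range-relative figures of merit — together
with a seeded synthetic-data generator that emulates a multi-site study, so
the whole calibration-transfer experiment is reproducible without
proprietary spectra.

## The model and its pipeline

The calibration model is linear: \(Y = XB + E\), with \(X\) the matrix of
preprocessed spectra, \(Y\) the analyte concentration (one PLS1 model per
analyte), \(B\) the regression coefficients and \(E\) the residuals. The
pipeline that produces \(X\):

1. **Grid standardization.** Each instrument reports intensities on its own
   wavenumber grid. All spectra are interpolated by a cubic spline onto the
   least-common-denominator grid 300–3399 cm⁻¹ in 3 cm⁻¹ steps (1034
   channels). 3400 cm⁻¹ is not reachable from 300 in steps of 3, so the
   stated upper limit of 3400 is treated as a bound and the grid ends at
   3399. We use the Forsythe–Malcolm–Moler end condition
   (`stats::splinefun(method = "fmm")`), which reproduces cubic polynomials
   to machine precision; the tests assert sub-1e-8 relative error on cubics.
   Extrapolation is never performed — a spectrum that does not cover the
   target grid is rejected.

2. **Savitzky–Golay first derivative** (2nd-order local polynomial, 31-point
   window). The derivative removes additive baseline structure (anything
   locally constant exactly; smooth fluorescence drift almost entirely) and
   sharpens overlapping bands. The derivative is taken per cm⁻¹ (the
   per-step filter output divided by the grid increment), so results do not
   depend on the grid spacing convention. Output is restricted to the
   interior channels where the full window fits: 15 channels are trimmed at
   each end (1034 → 1004). Edge channels are dropped rather than fitted
   asymmetrically: deterministic and artifact-free.

3. **Standard normal variate (SNV).** Each spectrum is centered and divided
   by its own standard deviation (sample SD, n − 1 throughout the package),
   removing per-spectrum offset and multiplicative scatter. A spectrum whose
   SD falls below a configurable floor (default 1e-10) is an error, not a
   silent division.

A *preprocessing fingerprint* (window, order, SNV flag, resulting grid) is
stamped on every preprocessed set and stored inside every fitted model;
predicting data whose fingerprint or grid differs from the model's is
refused. This guards against the central transferability pitfall: silently
applying a calibration to spectra that were preprocessed differently.

## PLS1, cross-validation, and model selection

Components are extracted by NIPALS with X-deflation only; \(X\) is
mean-centered but not variance-scaled per channel (SNV has already
normalized scale), \(y\) is centered. The coefficient vector for \(a\)
components is the standard closed form \(B = W (P^\top W)^{-1} q\). On a
full-rank problem with as many components as predictors, PLS predictions
coincide with ordinary least squares; the test suite asserts this against a
directly solved normal-equations oracle at 1e-8.

The latent-variable count is chosen by grouped k-fold cross-validation
(default 10 folds). Folds are formed over *batches*, never over individual
spectra: spectra within a batch are serially correlated, and a per-spectrum
split would leak near-duplicates across the train/validation boundary and
overstate performance. The same reasoning applies to the 70/30
calibration/test split, which assigns whole batches to one side while
targeting the 70% spectrum fraction as closely as batch sizes allow.

From the RMSECV curve (root mean square error of the pooled out-of-fold
predictions, per LV count) we select the **smallest LV count within 1% of
the curve minimum** rather than the raw argmin: RMSECV curves on real-scale
data are noisy and flat near the optimum, and the raw argmin systematically
overfits. The tolerance is configurable (`cv_config(tolerance = )`). When
the training data run out of rank before the scan maximum, the curve is
padded with its last value — extra components cannot be extracted and would
not change predictions.

## Figures of merit

For predictions \(\hat Y_i\) against references \(Y_i\):

\[
\mathrm{RMSE} = \sqrt{\tfrac1N \sum_i (\hat Y_i - Y_i)^2}, \qquad
\mathrm{SEC\ or\ SEP}(\%) = 100 \cdot \mathrm{RMSE} / Y_\mathrm{range},
\]

with \(Y_\mathrm{range}\) the highest minus the smallest reference value *of
the set being scored* (an external set uses its own range). SEC
(calibration) and SEP (prediction) use the identical formula — the role is
metadata, and every report row is re-checked for the identity
`sep_percent == 100 * rmse / yrange` at read time. \(R^2\) is fixed to the
coefficient-of-determination form \(1 - SS_{res}/SS_{tot}\) (the
"variability captured" reading); the squared-Pearson alternative is
available behind `r_squared(..., method = "pearson")` for cross-checking.
The conventional quality bands — below 5% very good, above 10% too high —
are attached to reports as annotations, never as hard failures. A 0–1
min–max scaling is provided for disclosure-free reporting; it is used only
for presentation, and SEP% is provably identical on scaled and raw values.

## What the synthetic generator emulates

No real spectra are distributed, so the study corpus is synthetic, generated
by seeded simulation with the statistical structure the analysis assumes:

* **Signal.** Each analyte contributes a concentration-linear sum of 3–4
  stylized Gaussian/Lorentzian bands. Band centers overlap between analytes
  (e.g. 1045/1060, 1090/1100/1125 cm⁻¹) so that no single channel resolves
  one analyte and the regression is forced to be multivariate. Glutamate's
  intensity coefficients are ~20-fold smaller than glucose's: it is by
  construction the weak, hard-to-calibrate analyte, and its concentrations
  stay in the low sub-g/L (few mmol/L) range. The bands are stylized, *not*
  spectroscopically curated cross-sections.
* **Matrix background.** A fixed water/medium pseudo-component (broad water
  bands plus a few sharper medium bands) dominates every spectrum. This is
  both physically realistic — the aqueous matrix dominates culture Raman —
  and statistically necessary: SNV divides by the per-spectrum SD, and
  without a dominant constant background that division would make the
  preprocessed signal visibly nonlinear in concentration, breaking the
  linear-model assumption.
* **Instrument character.** Each site's instrument has its own native grid
  (100–3425 @ 1 cm⁻¹ or 100–4000 @ 3 cm⁻¹), a constant wavenumber offset
  (miscalibration, +2.0/−1.2/+1.0/−1.6 cm⁻¹ across the four sites), a band
  broadening factor (0.97–1.08), additive channel noise, a per-spectrum
  random cubic baseline, and a per-spectrum log-normal scatter factor. The
  offsets are spread around zero so that no single site is centered but the
  pool is; the held-out validation unit is modeled as well-calibrated
  (offset 0). This is precisely the configuration in which pooling helps: a
  single-site model carries its own instrument's bias into the coefficients,
  while the pooled model averages the biases out. Degree-3 baselines were
  chosen from the plausible 3–5 band because higher degrees mainly add
  smooth per-site residual dimensions that survive the 2nd-order derivative
  and inflate the component count without changing the science.
* **Process.** Each batch is an independently seeded fed-batch trajectory:
  logistic biomass, glucose consumed between daily bolus feeds (so glucose
  increases only at feed events), lactate produced during growth and
  consumed after a randomized metabolic shift, glutamine fed and consumed,
  glutamate slowly exchanged at low level. Per-batch log-normal jitter
  (SD 0.25) on rates and setpoints makes batches genuinely different; this
  batch-to-batch diversity is what decorrelates glucose from lactate across
  the corpus, a prerequisite for a generic model. Spectra are emitted at
  evenly spaced sampling times over a 14-day run and paired with the
  trajectory concentrations at those times, so spectra and references arrive
  already matched (no time-alignment step is needed or provided).
* **Scale.** The full-scale configuration reproduces the multi-site corpus
  dimensions (305/958/295/148 spectra in 6/22/4/7 batches). The packaged
  desk-scale configuration (~10%: 30/96/30/15 spectra in 5/8/5/5 batches)
  is the default for the experiment driver and the test suite; it was sized
  so the complete transfer experiment runs in seconds while keeping enough
  batches per site for the grouped CV contract after a 70/30 batch split.
* **External validation.** The dilution series uses the printed levels
  (100, 50, 40, 30, 20, 11, 9, 7, 5, 3 g/L glucose, triplicate; reference
  range 97 g/L) on a fifth, held-out instrument. The stock composition
  co-diluted with glucose (lactate 20, glutamine 8, glutamate 3 g/L) is a
  design choice. The independent culture run uses a sixth instrument unit
  and a deliberately narrow, low glucose range (~2–4 g/L): absolute errors
  stay modest but the range-relative SEP% inflates, the known failure mode
  when a wide-range calibration meets a narrow-range application.

What the generator does **not** emulate: real Raman cross-sections and band
assignments, cell-density/product-titer signals, cosmic-ray spikes,
detector nonlinearity, medium-to-medium background differences, or
wavenumber-dependent instrument response. Passing tests therefore
demonstrate that the *pipeline* is correct and that pooling defeats the
modeled instrument variance — not that any particular real spectrometer
pair would transfer.

## Numerical choices

* Spline: FMM end condition; interpolation only (never extrapolation);
  standardizing a spectrum onto its own grid is the identity.
* SG filter: coefficients from `signal::sgolay`; window 31, order 2,
  derivative 1; uniform-grid check at 1e-8 relative; spectra shorter than
  the window are rejected.
* SD convention: sample SD (n − 1) everywhere (SNV, R², selection).
* NIPALS stop: a component is only accepted if its weight and score norms
  exceed 1e-10 relative thresholds; `fit_pls` errors if the requested count
  exceeds what the data rank supports.
* Ties in LV selection go to the smaller count.
* Seeding: every public generator takes an explicit integer seed; one master
  seed drives derived per-stage streams (`derive_seed`), all below 2³¹.
  Identical (config, seed) pairs give bit-identical outputs.
* Model serialization: JSON with 17 significant digits, which round-trips
  IEEE doubles exactly; a reloaded model predicts bit-identically.

## The packaged experiment

`run_generic_experiment()` executes the whole study at desk scale: pooled
generic models per analyte (calibration SEC%, batch-split test SEP%,
external dilution-series SEP%, and independent-culture SEP% for glucose and
lactate) plus per-site glucose models for the single-site versus pooled
comparison. At the packaged default seed the pooled glucose model's external
SEP% beats every single-site model, glucose and lactate stay well inside the
10% acceptability bound, and the glutamate analog is the clearly worst
analyte — the qualitative pattern the generic-model approach predicts. The
single-site-vs-pooled ordering is a property of the modeled conditions at
the packaged seed, not a theorem; individual seeds can produce a
well-matched single site.

Under the final study conditions the pooled models select 7–9 latent
variables for the strong analytes (scan maximum 20). The weak glutamate
signal does not drive its *selected* component count up under the
parsimony rule — its RMSECV curve is flat and noisy, so the rule collapses
it to few components; glutamate's difficulty shows instead in its external
error, which is the honest symptom of the same problem.

## Known limitations

* The synthetic peak library is stylized; no claim is made about real band
  positions or relative cross-sections.
* PLS2, variable/interval selection, outlier diagnostics (Hotelling T²,
  Q residuals), MSC/detrending preprocessing variants, and vendor binary
  formats are out of scope.
* The per-site concentration ranges, stock compositions and kinetics are
  modeling choices; only the dilution-series levels, corpus dimensions,
  instrument grid families and the preprocessing/selection conventions
  follow the published study design.
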