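---
title: "NGR drug-screen quantification: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NGR drug-screen quantification: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ngrscreen)
```

This vignette is the package's own account of the science it implements:
the growth-rate-normalized quantification of imaging-based drug screens,
the assumptions behind each stage, the parameters that matter, and what the
synthetic-data tests do and do not establish.

## 1. From segmented areas to NGR

The raw observable is a pair of areas per well per imaging timepoint:
total brightfield area (all cell material) and the dead-cell (green
fluorescence) area. Viability is their difference, floored at zero —
segmentation noise occasionally makes the green mask exceed the brightfield
mask, and negative viability has no physical meaning.

Fractional growth `G = (V(x) − V(0))/V(0)` is normalized per plate to the
two control anchors: the median vehicle-control growth `GmedNeg` (must be
positive — cells must grow untreated) and the median positive-control
(staurosporine) growth `GmedPos` (must be negative — the kill control must
kill). Plates violating either sign are rejected as QC failures rather than
normalized into nonsense. Controls are summarized per plate and treated
wells are normalized against their *own* plate's controls; plate-to-plate
effects are precisely why the controls are on every plate.

The normalization itself is branch-wise:

* `G > 0`: `NGR = G / GmedNeg` — growing wells are scored against normal
  growth;
* `G < 0`: `NGR = −(G / GmedPos)` — shrinking wells are scored against the
  kill control. The leading minus is deliberate. The unsigned form of this
  branch (which does appear in print) assigns +1 to a well that dies
  exactly like the positive control, contradicting the scale's own legend
  (−1 = complete killing). Only the signed form makes the anchors
  `NGR(GmedNeg) = +1`, `NGR(GmedPos) = −1` and the cytostatic/cytotoxic
  classification internally consistent, so the signed form is what this
  package computes. The discrepancy is documented, not hidden.
* `G = 0` maps to 0: both branches limit to 0, so the scale is continuous
  at complete growth inhibition.

NGR is clipped to `[−1, 1]` before any curve fitting; the unclipped value
is retained alongside for diagnostics (it is the only way to see
proliferative responses, NGR > 1). Whether a published analysis clips
before or after fitting is typically unstated; fitting on clipped values is
the conservative reading of a definition in which the clip precedes the
model, and it is the choice made here, once.

Because every quantity is a ratio of areas from the same plate, NGR is
invariant to rescaling all areas by a constant — area units never matter,
and the package treats areas as unitless throughout.

## 2. The GR dose–response model and its fitting

The concentration response is modeled by the sigmoidal GR equation
`GR(c) = GRinf + (1 − GRinf)/(1 + (c/GEC50)^h_GR)`, whose three parameters
have direct pharmacological readings: `GRinf` is the plateau response at
saturating drug (negative = net cytotoxic, 0 = purely cytostatic, 1 =
inert), `GEC50` the concentration of half-maximal effect, and `h_GR` the
transition steepness. Anchors used as test oracles: `GR(0) = 1`,
`GR(GEC50) = (1 + GRinf)/2`, `GR(∞) = GRinf`.

Fitting is per cell line × drug × biological replicate (each replicate
carries its own wells, so a 7-dose screen with 2 wells per dose yields 14
points per fit). Choices that were genuinely open, and how they were
settled:

* **Optimizer.** Bounded least squares via `optim(L-BFGS-B)` on
  `(GRinf, log10 GEC50, h_GR)`, followed by a damped Gauss–Newton polish
  with the analytic Jacobian. `nls()` was rejected because it errors on
  zero-residual data — exactly the noise-free synthetic case the recovery
  tests require. The polish matters: quasi-Newton alone stalls ~1e−6 away
  from the optimum on noise-free data, while the polish reaches machine
  precision (the end-to-end recovery tests assert 1e−4 relative; measured
  worst case across the 24-triple truth grid is ~3e−15).
* **Start values** are fixed at `GRinf = 0.1`, `GEC50 =` median tested
  concentration, `h_GR = 2` — the standard GR-fitting initialization.
* **Bounds** `GRinf ∈ [−1, 1]`, `GEC50 ∈ [c_min/10, 10·c_max]`,
  `h_GR ∈ (0, 10]` are imposed although the classical recipe names only
  start values: without them, plateaued (drug-inert) data sends `GEC50`
  diverging. Degenerate all-ones profiles then land on some inert curve
  with AOC ≈ 0, which is the scientifically correct summary even though
  the individual parameters are unidentifiable.
* **Outlier rule.** A point is an outlier iff `|r| > 2.5 · mean(|r|)` *and*
  `|r| > 0.25`; the conjunction means homogeneous noise never triggers it
  and small residual scales cannot amplify trivia. The pass runs exactly
  once after the first convergence — no iterating until quiescence — and if
  removal would leave fewer than 4 points the original fit is kept and
  flagged `refit_skipped`. Non-converged fits are reported with
  diagnostics, never dropped silently.
* **Readout timepoint** defaults to the final imaging time (120 h), where
  cytostatic and cytotoxic outcomes have had time to separate;
  configurable.

## 3. NGR50 and AOC

`NGR50` solves `GR(c) = 0.5` in closed form,
`GEC50 · (0.5/(0.5 − GRinf))^(1/h_GR)`, defined only when `GRinf < 0.5`;
otherwise, or when the root lies above the top tested dose, the value is
right-censored as `"> c_max"` rather than extrapolated. The closed form is
property-tested against numeric root-finding at 1e−9 relative.

The AOC integrates `1 − GR(c)` over **log10 concentration** across the
**tested range only**, and normalizes by the maximum attainable area
(`2 ×` the log-range, since the curve floors at −1), giving AOC ∈ [0, 1]
with interpretable anchors: 0 for an inert drug, 0.5 for complete
cytostasis everywhere, 1 for complete killing everywhere. Neither the
integration variable nor the range is ever stated alongside published AOC
values; log-concentration over the tested range is the only choice that
(a) weights each titration decade equally, (b) needs no extrapolation
beyond data, and (c) lands published-magnitude values (≈ 0.08–0.63) on a
[0, 1] scale. Quadrature is composite trapezoid on ≥ 256 log-spaced points
(default 513) with the curve clipped to [−1, 1] inside the integrand;
doubling the grid moves the result by < 1e−6.

## 4. Fold changes and the statistical layer

Sensitivity differences are summarized as signed AOC fold changes:
`+test/ref` when the test line's AOC is larger, `−ref/test` when smaller,
so the magnitude is always the ratio of larger to smaller (≥ 1), the sign
encodes direction, and `fc(a,b) = −fc(b,a)`. This convention is
reverse-engineered from how published mutant-vs-wild-type comparisons are
reported (a resistant mutant gets a negative fold change whose magnitude is
the wild-type/mutant AOC ratio); it reproduces the published 3D ceritinib
−2.8 and entrectinib −2.02 examples from the printed AOC table within
rounding. Fold changes of non-positive AOCs are reported as errors, never
clamped.

Replicate-level AOCs are compared by two-way ANOVA (`AOC ~ cell_line *
drug`), with normality and homoscedasticity assumed, 2D and 3D analysed
separately — matching how such results are reported — and the interaction
included, since per-drug contrasts presuppose cell-level structure within
drug. Each non-reference line is tested against the reference within each
drug; the family for multiplicity adjustment is the set of many-to-one
contrasts for that drug.

The Dunnett adjustment is computed exactly rather than delegated: given
the contrasts' shared dependence on the control mean and the pooled SD,
`P(max_i |T_i| ≤ q)` is a two-dimensional integral over the control's
standardized mean (normal) and the SD factor (scaled chi), evaluated by
Gauss–Legendre quadrature with 96 nodes per dimension mapped through the
respective quantile functions. Accuracy: ~1e−5 against the exact `k = 1`
reduction (a t distribution) and within Monte-Carlo error of a 2×10^5-draw
simulation oracle in the tests — comfortably inside the documented 1e−3
tolerance on adjusted p-values. Adjusted p-values are additionally floored
at the unadjusted value, preserving the `p_adj ≥ p_unadj` invariant against
residual quadrature error. Calibration is verified by simulation: under a
4-genotype null with n = 4 the per-drug family-wise false-positive rate
over 1000 seeded runs stays ≤ 0.07 at α = 0.05, and a 5-pooled-SD shift is
detected in ≥ 95% of 200 runs.

## 5. What the synthetic generator emulates — and what it does not

The generator states a world once and the tests live in it: a 384-well
plate per cell line per replicate, a 7-point logarithmic titration spanning
1–5000 nM, imaging every 24 h to 120 h, vehicle and staurosporine-like
control wells, and ground-truth GR curves per cell line × drug. Treated
endpoint growth is the *inverse* NGR mapping of the truth curve
(`G = r·neg_growth` when `r ≥ 0`, `−r·pos_growth` when `r < 0`), so with
zero noise the pipeline must reproduce the truth exactly — the basis of the
recovery tests. Choices not stated anywhere upstream, fixed once:

* `neg_growth = +1.0` over 120 h (one doubling) and `pos_growth = −0.9`
  (near-complete kill). All downstream quantities are ratios to these, so
  noise-free results are invariant to the choice; they are stand-ins, not
  measurements.
* Growth between timepoints interpolates geometrically in `(1 + G)` —
  smooth, positive trajectories; only endpoint quantities are defined
  upstream.
* Dead-cell area is the shortfall of viability below vehicle-like
  potential growth (detectability factor 1), so `total − dead` equals the
  modeled viability by construction; the green channel is not modeled
  quantitatively anywhere upstream and only the difference matters
  downstream.
* Noise is multiplicative lognormal (unit mean, stated CV, default 0.05)
  on the two *measured areas*, the physical observables — not on growth
  rates.
* Scenario parameters in `default_scenarios()` (sensitive WT at tens of
  nM; resistant line at ~1.5–2 µM with near-zero maximal effect; a
  `GRinf = 0` cytostatic plateau; an attenuated 2D regime with 4
  replicates) are chosen to echo the qualitative regimes of a TKI
  resistance screen at magnitudes a screening lab would call realistic.

What a green test therefore establishes: the estimator pipeline is
*internally correct* — it inverts its own generative model to machine
precision, degrades gracefully under realistic measurement noise (median
GEC50 error ~18% at CV 0.05 with 4 wells/dose), and its statistics are
calibrated. What it does not establish: that real segmentation output
behaves like lognormal area noise (no spatial/edge effects, no
segmentation failure modes, no well-to-well contamination is modeled), nor
that published absolute AOC values are recovered — those depend on the
wet-lab screen and enter only as printed inputs to the fold-change
examples.

## 6. Numerical and degenerate-input policy

* Viability floored at 0; wells with non-positive *baseline* viability are
  excluded with a warning naming the wells (an exclusion is auditable; a
  silent zero is not).
* Dose-grid membership uses 1e−6 relative tolerance, so a display-rounded
  "17 nM" is (correctly) rejected against the true grid point 17.0998 nM.
* Ties at `G = 0` map to NGR 0 exactly; the `normal` classification uses a
  1e−6 tolerance around 1.
* All validation failures raise typed conditions (`ngr_schema_error`,
  `ngr_integrity_error`, `ngr_qc_error`, ...), never silent drops.
* Determinism: the simulator seeds its own RNG stream and restores the
  caller's; identical configs give bit-identical tables, and a fixed-seed
  pipeline run is byte-identical including its manifest (no timestamps).

## 7. Known limitations

* One fit per replicate with metrics averaged afterwards; no pooled or
  mixed-effects alternative is offered.
* The Dunnett layer assumes the ANOVA's homoscedastic normal model, as the
  upstream procedure states; it is not robustified.
* NGR50 censoring is reported but censored values are simply excluded from
  replicate means (with a count), not survival-modeled.
* Only the GR family is fitted — no biphasic or raw-viability 4PL models,
  and no IC50-on-viability computation.
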