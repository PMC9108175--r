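---
title: "Validating youth wrist cut-points: models, generator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating youth wrist cut-points: models, generator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristcutpoints)
```

## The validation design

Cut-point classification of physical-activity intensity assumes that a
threshold on an epoch-level accelerometer metric separates adjacent
intensity categories. The laboratory design this package implements tests
that assumption directly: children perform structured activities spanning
sedentary to vigorous intensity while wearing wrist accelerometers on both
sides and a portable calorimeter; each trial is summarised over a steady
window; the calorimetry defines measured intensity; each cut-point set
predicts intensity from its own metric and wear side; and agreement is
quantified on the ordinal four-level scale.

The chain is: raw 30-Hz tri-axial signal → autocalibration → 1-s ENMO;
device counts → per-5-s vector magnitude; both → window means → predicted
labels per cut-point set; gas exchange → window-mean VO2 → Youth METs →
measured label; paired labels → confusion matrices, weighted kappa,
per-class accuracy, per-activity misclassification direction.

### Ground truth

Youth METs divide mass-relative VO2 by *predicted resting* energy
expenditure rather than the adult 3.5 ml kg⁻¹ min⁻¹ constant, because
children's resting metabolism varies strongly with age and size. REE comes
from the Schofield weight-and-height equations; the weight-and-height
variant (not weight-only) is used because height is among the predictors
the design names. The coefficients are stored in one table in
`R/energy.R`; the energy equivalent of oxygen (default 20.9 kJ/L) is an
argument, since the literature also uses 20.35.

Boundary handling is exactly as published: SED requires a lying or sitting
posture *and* < 1.5 Youth METs; 1.5 maps to LPA, 3 to MPA, 6 to VPA; an
upright trial below 1.5 METs is LPA, not SED. Posture is taken from the
activity catalogue, not inferred from the signal.

### Cut-point semantics

Each set retains its published comparison conventions verbatim instead of
being normalised: the Crouter sets treat a value equal to the SED
threshold as sedentary (`x ≤ 105`), while Chandler and Hildebrand use a
strict inequality (`x < 161`, `x < 35.6`). Moderate and vigorous are `≥`
everywhere. For the two Crouter regression sets, classification uses the
printed count thresholds; the regression equation itself is exposed
separately (`regression_mets()`), and inverting it at 3 and 6 METs with
integer rounding reproduces the printed thresholds (`invert_regression()`)
— a consistency check the test suite and `scripts/acceptance.R` both
exercise. Wear side follows the calibration provenance of each set:
Crouter sets read the dominant wrist (the handedness side), Chandler and
Hildebrand the non-dominant.

### Agreement

Weighted kappa is computed from the defining disagreement form
`κ_w = 1 − Σ w·o / Σ w·e` with weights `|i−j|/3` (linear, the default),
`((i−j)/3)²` (quadratic) or 0/1 (unweighted). The design this package
follows does not name its weighting scheme; linear is the conservative
default for an ordinal four-level outcome, and reports always name the
scheme. The standard error is the Fleiss–Cohen–Everitt large-sample
formula with a normal 95 % interval clipped to \[−1, 1\]; a matrix whose
mass sits entirely in one row-and-column cell has no chance disagreement,
so kappa is returned as `NA` with a `degenerate` flag rather than a
contrived value. Per-class accuracy is diagonal over row sum, with empty
measured classes reported as missing, not zero. The test suite checks the
kappa implementation against an independent brute-force evaluation of the
defining formula on 200 random matrices (absolute agreement to 1e-12).

## The synthetic cohort generator

No participant-level data are distributed with the design, so the
generator recreates a cohort whose *trial-level* distributions match the
published per-activity summaries: mean ± SD Youth METs and median/IQR of
VA counts, VM counts and ENMO for each of the 12 activities, plus the
cohort demographics (ages Normal(14.6, 2.4) truncated to \[8, 18\], 10:8
male:female, 90 % right-handed) and the scheduling arithmetic (216
scheduled trials, dropout 34/216 with four failure modes).

Key mechanisms, all with defaults fixed once and exposed in
`trial_config()` / `cohort_config()`:

- **Median/IQR → lognormal.** Counts and ENMO are non-negative and
  right-skewed, so each activity's metric level is lognormal with
  `μ = log(median)` and `σ` solved from the IQR width
  (`2·median·sinh(z₇₅σ) = q3 − q1`). Zero-median metrics (lying-down
  counts, handwriting ENMO) use a zero-inflated lognormal with inflation
  1/2, whose non-zero branch has `μ = log(q3)` (so the mixture's upper
  quartile is preserved) and `σ = 0.5`.
- **Latent intensity coupling.** One latent factor per trial drives the
  MET draw and, with loading 0.7, the metric draws; left and right wrists
  correlate at 0.8. Both reflect the same physical reality — a vigorous
  trial is vigorous in every signal — and without the coupling, quiet
  trials with large metric draws are far too common.
- **Raw signal.** Gravity along a random fixed orientation plus a
  half-wave-rectified sinusoid (1–3 Hz) along it, scaled so the windowed
  ENMO equals the drawn target exactly (`amplitude = π · target`), with
  2 m*g* sensor noise, distorted by the device's gain/offset error. The
  half-wave rectification keeps the sample norm at `1 + s ≥ 1`, so the
  identity `mean ENMO = amplitude/π` holds at any amplitude.
- **Counts.** Drawn at the 5-s epoch level directly (the count algorithm
  is proprietary, and validation designs treat counts as device output);
  epoch jitter is mean-corrected lognormal with σ = 0.15, `VM ≥ VA` is
  enforced per epoch, and the ML/AP axes split the VM residual evenly.
- **Physiology.** VO2 ramps mono-exponentially (τ = 45 s) from rest
  (1 MET) to the plateau implied by the drawn METs, mass and Schofield
  REE, with 2 % multiplicative noise; heart rate is affine in METs
  (65 + 12.5·METs bpm) with a faster ramp (τ = 30 s) and 1.2 bpm noise —
  calibrated so that honest trials pass the ±5-bpm/10 % steady-state check
  at the analysis window.

### What the generator does *not* emulate

Trial draws are independent across participants and activities given the
activity — there are no participant random effects (a child who walks
fast walks fast in every walking trial), no activity-specific frequency
content in the raw signal, no autocorrelated count bursts, no non-wear,
and no count/raw consistency (counts and ENMO are coupled only through
the latent factor, not through a shared simulated movement). Passing
distribution-fidelity tests therefore shows the pipeline handles data *of
the published shape* correctly; it does not certify behaviour on real
free-living recordings.

Two structural consequences are worth knowing. The published slow-walk VA
IQR (220–287 counts/5 s) straddles the Crouter ROC moderate threshold
(262), so under any marginal-matching generator a substantial minority of
slow-walk trials classify as MPA and the under-estimation fraction for
that set hovers near one half rather than clearly above it. And the
lognormal fitted to the computer-game ENMO summary (median 8.5, IQR
1.8–21.1 m*g*) has a heavy right tail across the 35.6 m*g* sedentary
threshold, so the ENMO set's sedentary-row accuracy is more fragile in
simulation than in the bounded real data. The end-to-end checks in
`tests/testthat/test-acceptance.R` assert the stricter qualitative claims
anyway, and their outcome on the fixed default cohort (seed 1) is the
recorded, unembellished result.

## Signal-processing choices

- **Autocalibration** fits per-axis gain and offset so still-window means
  lie on the unit gravity sphere, by iteratively projecting onto the
  sphere and regressing per axis (stop when the RMS residual changes by
  < 1e-6, cap 100 iterations). Still windows are non-overlapping 10-s
  windows with every axis SD < 13 m*g*. The fit requires ≥ 10 still
  windows *and* ≥ 0.3 g of per-axis spread in the still-point cloud —
  one posture cannot separate gain from offset — otherwise the identity
  is returned unconverged and the caller falls back to it. These
  constants follow common raw-accelerometry practice and are arguments.
- **ENMO epoching** is 1 s (the unit of the ENMO cut-point set); the
  trial feature is the mean over the window, which is identical whether
  the averaging passes through 1-s or 5-s epochs.
- **Windows** are half-open `[150, 270)` s from trial start (lying:
  `[420, 540)`), exactly 120 s; epochs are half-open `[t, t + len)`.
- **Steady state** is `max |x − mean(x)| ≤ tol` within the window, with
  ±5 bpm for heart rate and 10 % of the window mean for VO2.

## Problem sizes and runtime

The distribution-fidelity check simulates 500 trials per activity
(6 000 trials) and compares simulated feature medians with the published
IQRs, requiring agreement for at least 10 of 12 activities; the
end-to-end check runs one full default cohort (18 × 12 trials at 30 Hz)
through simulation, feature extraction and agreement analysis. Both
complete in a few minutes on a single core; the kappa oracle, calibration
recovery and exact-constant checks run in seconds.

## Known limitations

- Anthropometry uses an internal reference table of age/sex median mass
  and height with lognormal spread; the real cohort's anthropometry is
  unpublished, so Schofield REE values are realistic but not
  cohort-matched.
- The kappa CI method and weighting scheme of the original design are
  unstated; results are therefore comparable in kind, not bit-for-bit,
  even with identical data.
- Real count data are integer-valued band-pass accumulations with strong
  autocorrelation; simulated counts match marginal medians/IQRs only.
- `evaluate_dataset()` autocalibrates each trial recording from its own
  300–600 s series; recordings that never rest in varied orientations
  (most moving trials) fall back to the identity, which is correct for
  well-calibrated devices but leaves simulated gain/offset errors
  uncorrected in ENMO when `gain_jitter`/`offset_jitter_g` are set above
  their default of 0. Calibrating from a longer wear period, as raw
  processing suites do, is out of scope.
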