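---
title: "Micropattern FRAP: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micropattern FRAP: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patternFRAP)
```

## The measurement problem

TIRF FRAP at the plasma membrane of a living cell reports a mixture of
processes: exchange of the labeled protein at its membrane receptor,
diffusive refilling of the bleached cytosolic pool, and slower
contributions of unclear origin (cortical trapping, transient membrane
association, diffusion gradients created by the bleach pulse itself).
Fitting a whole-cell recovery curve therefore overestimates binding
time constants. When the receptor is immobilized on a micropatterned
antibody grid (1 µm dots, 3 µm pitch), receptor-depleted "OFF" areas
of the same cell experience every non-specific contribution while only
the "ON" dots add specific binding. The per-dot difference
ΔF = F_ON − F_OFF cancels the shared terms, and the corrected ΔF curve
is well described by a single exponential whose time constant is the
unbinding time of the protein-receptor interaction.

## Recovery models

Two empirical models are fitted, both in recovery orientation (rising
from the offset `b` toward the mobile fraction `f_m`):

* mono-exponential: `F(t) = (f_m − b)(1 − exp(−t/τ)) + b`, used for
  corrected ΔF curves;
* bi-exponential:
  `F(t) = (f_m − b)[1 − c·exp(−t/τ1) − (1 − c)·exp(−t/τ2)] + b`, used
  for ON/OFF and whole-cell curves, where `c` is the fraction of the
  fast component.

`mono_exp_model()` also exposes a literal decaying form
(`orientation = "decay"`, `F(t) = (f_m − b)·exp(−t/τ) + b`) for
completeness; recovery is the default and the orientation used
everywhere in fitting, because corrected ΔF traces rise toward `f_m`.
The bi-exponential model is invariant under swapping `(τ1, c)` with
`(τ2, 1 − c)`; constructors and fits canonicalize to `τ1 < τ2` so that
cohort statistics over components are well defined.

Parameter meanings and defaults:

| parameter | meaning | bounds in fitting |
|---|---|---|
| τ, τ1, τ2 | exponential time constants (s) | 1e-3 – 1e4 |
| f_m | mobile (recovered) fraction | 0 – 1.5 |
| b | offset: incomplete bleaching plus recovery during the 500 ms pulse before the first frame at 6 ms | 0 – 1 |
| c | fraction of the fast component | 0 – 1 |

The upper bound of 1.5 on `f_m` deliberately admits above-100%
recovery, which occurs when dim dots gain material during the recovery
phase; such fits are retained and only excluded from cohort summaries
if they pin at a bound.

## Acquisition protocol and time base

One pre-bleach frame (5 ms exposure) is followed by a 500 ms bleach
pulse and 50 post-bleach frames whose times are evenly spaced on a
logarithmic axis starting 6 ms after the pulse. The logarithmic
spacing samples the sub-second cytosolic component and the
tens-of-seconds binding component with comparable point density, which
is also why unweighted least squares is adequate. The total
post-bleach window is not a fixed property of the protocol; the
package default is 120 s, chosen because the slow components
(τ2 ≈ 10–20 s) plateau within a few time constants, and it is
configurable in `acquisition_protocol()`.

## Correction chain

Corrections are applied in a fixed, flag-guarded order; each step
records itself on the curve and re-application is either a no-op
(normalization) or an error (divisions):

1. **Background**: per-frame mean over a dot-free region is subtracted
   from every ROI mean.
2. **ΔF per dot**: OFF is subtracted from ON separately for each dot,
   *before* pooling, so each dot's local OFF reference is used.
3. **Pooling**: pointwise mean over the retained dots of a cell
   (typically ~7 dots).
4. **Pre-bleach normalization**: division by the pre-bleach value.
   ΔF curves are normalized by their own pre-bleach ΔF; this makes the
   mono-exponential `f_m` directly comparable to the bi-exponential
   `f_m` of whole-cell fits, which cohort tables require.
5. **Acquisition-bleach correction**: pointwise division by a paired
   no-bleach control curve (same timing, bleach pulse replaced by
   standby), normalized to its own pre-bleach value. An empirical
   control is used rather than a fitted bleaching model.
6. **Depletion correction**: post-bleach points are divided by
   `1 − d`, where `d` is the fraction of the detected pool destroyed
   by the bleach pulse (~12%, i.e. divisor 0.88 at 22 °C and 0.85 at
   37 °C). The pre-bleach point measures the undepleted pool and is
   not rescaled.

Negative ΔF values produced by noise are retained; clipping them would
bias the offset estimate upward.

`d` is estimated by `estimate_depletion()` from a repetitive-bleach
protocol (five 500 ms pulses 1.5 s apart, one readout 1 s after each
pulse): per pulse the relative change (pre − post)/pre is computed,
pulse 1 — which additionally bleaches slowly exchanging structures —
is discarded, pulses 2–5 are averaged per cell, and the cohort value
is the unweighted mean over cells (the choice of mean over median is a
declared convention). The estimator uses only ratios and is invariant
to intensity scale.

## Masking

Masks are built once from the pre-bleach frame and applied unchanged
to all post-bleach frames. The ON region is the largest square
inscribed in the dot (7×7 px for 1 µm dots at 0.1 µm pixels); the OFF
region is a rectangular annulus starting 2 px outside the ON square
and ending at 2/3 of the half-pitch, dimensions chosen so neighboring
annuli never touch neighboring dots. These sizes are declared defaults
(`build_masks()` arguments), since no canonical values exist; an
escape hatch accepts user-supplied centers or masks. Dots whose
annulus would cross the image or cell boundary are skipped rather than
clipped, keeping ON/OFF pixel counts comparable across dots. Only dots
with pre-bleach contrast (F_ON − F_OFF)/F_ON ≥ 0.4 enter the analysis.

Dot detection is automated (the manual alternative being ImageJ ROIs):
mean-filter smoothing, pitch-constrained local maxima above a relative
threshold (default half of the background-to-peak range), greedy
non-maximum suppression at half-pitch distance, and iterative
intensity-weighted centroid refinement restricted to the upper half of
the local intensity range — the restriction prevents the uniform
in-cell level around a dot from pulling the centroid toward the window
center. On synthetic grids this recovers centers to well under a
pixel, with or without noise.

## Fitting

`fit_mono()`/`fit_bi()` use bounded Levenberg–Marquardt least squares
(minpack.lm) on the post-bleach points only. Starting values are
deterministic: `b` from the first post-bleach value, `f_m` from the
mean of the last three points, mono τ from the half-recovery time. The
bi-exponential problem is ill-conditioned (sums of exponentials), so a
fixed 3×3 multi-start grid τ1 ∈ {0.1, 0.3, 1} s × τ2 ∈ {5, 15, 30} s
is tried and the converged fit with the lowest residual sum of squares
wins; identical data therefore always yield identical fits. Fits with
τ2/τ1 < 3 are flagged `poorly_separated` but not discarded. Standard
errors come from the fit covariance; non-convergence and bound-pinning
are reported in flags, never silently. Weighting is uniform — the
logarithmic time base already balances the fast and slow regimes.

Fits are performed separately per cell (`fit_cell()`): patterned cells
get a mono-exponential fit of their ΔF curve, coated-surface cells a
bi-exponential fit of the whole-cell curve extracted from the basal
membrane (edges excluded via an eroded cell mask when images are
used). Cohort summaries (`summarize_cohort()`) report mean ± SEM per
parameter by surface type, temperature and time group (a single
5–45 min group at 22 °C; 5–15 vs 25–45 min at 37 °C, split at 20 min);
non-converged or bound-pinned fits are excluded with counts reported.
No correction is attempted for the uncertainty in the seeding-time
axis (cells touch down at different times); the time group is taken at
face value.

## What the synthetic generator emulates — and what it does not

The generator produces every input the analyzer accepts, with ground
truth returned alongside:

* **OFF signal**: a bi-exponential with a fast cytosolic component
  (τ1 ≈ 0.3 s) and a slow non-specific component (τ2 ≈ 10–15 s). This
  is a phenomenological stand-in — no reaction–diffusion PDE is
  solved, because the analysis never needs the mechanistic origin of
  the OFF shape, only that ON and OFF share it.
* **ON signal**: OFF plus a mono-exponential binding component whose
  amplitude is set by the pre-bleach dot contrast (default 0.5).
* **Depletion** (default d = 0.12) multiplies all post-bleach values;
  **acquisition bleaching** is a per-frame multiplicative loss
  (default 0.002/frame) — per-frame rather than per-second because
  exposures are constant while inter-frame delays grow
  logarithmically.
* **Noise**: additive Gaussian with sd relative to each trace's
  pre-bleach level (default 0.02), optionally per-pixel in image mode.
  Camera statistics of the real instrument (EMCCD excess noise, shot
  noise) are not modeled; Gaussian noise at the observed scatter keeps
  least squares well-posed and is adequate for testing estimator
  behavior.
* **Calcium traces**: 1 Hz, 10 min, normalized to 1 at t = 0;
  activated cells rise sigmoidally by 0.6–1.2 with onset in the first
  5 min, non-activated cells drift below 0.25. The activation
  threshold of 0.4 is read as a rise of more than 0.4 *above* the
  normalized baseline (strict inequality) — the only reading
  consistent with normalizing traces to 1 at time zero. A trace
  peaking exactly at 1.4 is not activated. Segmentation and tracking
  of the underlying ratio images are out of scope; the module consumes
  traces.

Because the generator and the analyzer share the model family,
noiseless round-trips are exact by construction (the corrected ΔF
equals the generative binding model to machine precision); these
identity tests validate the correction algebra, not the biological
realism of the model. Passing parameter-recovery tests demonstrates
that the pipeline is unbiased under its own generative assumptions —
real data can violate them (non-exponential cytosolic recovery, drift,
heterogeneous dot brightness), which is precisely why the ΔF
construction, not the curve model, carries the method.

All simulators require an explicit seed; there is no hidden RNG state,
and equal seeds give bit-identical outputs.

## Numerical choices and degenerate inputs

* Time base: geometric progression from the 6 ms first delay to the
  total duration; a 3-point protocol from 1 s to 100 s gives exactly
  {1, 10, 100} s.
* Normalization requires a positive pre-bleach value; control curves
  containing zeros are rejected rather than producing infinities.
* Constant (fully degenerate) curves leave τ unidentifiable: the fit
  either reports `converged = FALSE` or pins τ at a bound with an
  `at_bound` flag — both are surfaced, and such fits are excluded from
  cohort summaries.
* Depletion divisors outside (0, 1] are configuration errors.
* Cohort groups with a single usable cell report `NA` SEM and a
  `single_cell_group` flag instead of a misleading zero.

## Problem sizes used in the test-suite simulations

Cohort-level checks simulate 8–34 cells with ~7 dots each at noise
sd 0.02, matching the cohort sizes of the study design the package
targets; recovery is asserted against the generative truth within
twice the cohort SEM of the corresponding reference group. Replicate
ladders for estimator-consistency checks use 30–60 fits per noise
level. These sizes give stable statistics while keeping the full suite
in the tens of seconds on a single core.

## Known limitations

* The exponential family is empirical; it does not correctly describe
  diffusion-dominated early recovery, and extracted τ1 values should
  not be over-interpreted mechanistically.
* Frame-to-frame drift is not corrected; masks from the pre-bleach
  image assume a registered series.
* The depletion correction is a single scalar per temperature; any
  dot-to-dot variation in depletion is averaged over.
* Bi-exponential fits remain ill-conditioned at realistic noise even
  with multi-start; the `poorly_separated` flag should be consulted
  before interpreting individual-cell τ1/τ2 splits.
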