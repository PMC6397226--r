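# patternFRAP

Measuring how long a cytosolic signaling protein stays bound to a
membrane receptor is hard with conventional FRAP: the fluorescence
recovery over the receptor mixes the binding kinetics of interest with
cytosolic diffusion and other non-specific contributions. patternFRAP
implements the micropattern solution for TIRF FRAP data: the receptor
(e.g. the T cell receptor, captured by stamped antibody dots of 1 µm
diameter at 3 µm pitch) is immobilized at defined "ON" spots, the
surrounding "OFF" areas of the same cell see every contribution
*except* specific binding, and the per-dot difference

ΔF(t) = F_ON(t) − F_OFF(t)

isolates the receptor-binding component. The corrected ΔF curve
follows a mono-exponential recovery

F(t) = (f_m − b)(1 − e^(−t/τ)) + b

whose time constant τ is the unbinding (exchange) time constant and
whose plateau f_m is the mobile fraction; b absorbs recovery during
the bleach pulse. ON, OFF and whole-cell curves on uniformly coated
surfaces are described empirically by the two-component form

F(t) = (f_m − b)\[1 − c·e^(−t/τ₁) − (1 − c)·e^(−t/τ₂)\] + b.

The package is aimed at quantitative microscopists: it covers ON/OFF
mask construction with a contrast ≥ 0.4 dot filter, background
correction, per-dot ΔF, pooling, pre-bleach normalization, division by
a no-bleach control curve (acquisition photobleaching) and by 1 − d
(bleach-pulse depletion, estimated from repetitive-bleach series),
bounded nonlinear least-squares fitting per cell, cohort aggregation
(mean ± SEM by surface type, temperature and time after seeding), and
activation classification of ratiometric calcium traces. A
synthetic-data generator with known ground truth (ROI traces, TIFF
image series, control/repetitive-bleach series, calcium traces) makes
every stage verifiable by parameter recovery.

## Worked example

Simulate a patterned cell with known binding kinetics, run the full
correction chain, and refit:

```r
library(patternFRAP)

gt <- frap_ground_truth(
  binding = mono_exp_params(tau = 14.6, f_m = 0.78, b = 0.12),
  noise_sd = 0.02)

sim  <- simulate_roi_traces(gt, n_dots = 7, seed = 1)
ctrl <- simulate_control_series(gt, seed = 2)
ctrl_curve <- recovery_curve(ctrl$trace$t, ctrl$trace$intensity,
                             ctrl$prebleach, kind = "CONTROL",
                             corrections = c(background = TRUE))

curve <- corrected_delta_curve(curves_from_traces(sim),
                               control  = ctrl_curve,
                               depletion = depletion_correction(d = 0.12))
fit_mono(curve)
```

```
mono-exponential fit (converged, n = 50, RSS = 0.03056)
Mono-exponential parameters: tau = 14.3 s, f_m = 0.7677, b = 0.1203
```

The fitted triple recovers the generative values (τ = 14.6 s,
f_m = 0.78, b = 0.12) to within the scatter expected at 2% intensity
noise: the protein exchanges at the receptor with a ~14-15 s time
constant and ~22% of the pre-bleach signal does not recover on the
2-minute observation window (stably bound fraction).

Depletion estimation and calcium classification follow the same
pattern:

```r
s <- simulate_repetitive_bleach_series(
  frap_ground_truth(noise_sd = 0, depletion = 0.12), seed = 1)
estimate_depletion(s)$divisor    # 0.88

ca <- simulate_calcium_traces(1000, activation_probability = 0.64, seed = 1)
percent_activated(ca$traces)$percent   # 63.7
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/patternfrap.R` (`simulate`, `analyze`, `estimate-depletion`,
`calcium`).

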