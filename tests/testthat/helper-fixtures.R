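# Shared fixtures: representative printed parameter sets and small
# builders for corrected curves on the default logarithmic time base.

default_tb <- make_timebase(acquisition_protocol())

# mono-exponential dF parameters of a representative patterned cell
rep_delta_mono <- mono_exp_params(tau = 18.1, f_m = 0.73, b = 0.02)

# bi-exponential parameters: representative non-activated cell,
# representative coated-surface cell, and non-activated cohort means
rep_nonactivated_bi <- bi_exp_params(tau1 = 0.57, tau2 = 17.4, f_m = 0.83,
                                     b = 0.29, c_frac = 0.80)
rep_coated_bi <- bi_exp_params(tau1 = 0.26, tau2 = 17.0, f_m = 0.77,
                               b = 0.03, c_frac = 0.47)
cohort_nonactivated_bi <- bi_exp_params(tau1 = 0.29, tau2 = 12.6,
                                        f_m = 0.89, b = 0.35, c_frac = 0.67)

# cohort-mean ground truths: patterned at 22 C, and the late 37 C group
patterned_22C_mono <- mono_exp_params(tau = 14.6, f_m = 0.78, b = 0.12)
patterned_37C_late_mono <- mono_exp_params(tau = 4.7, f_m = 0.57, b = 0.05)

all_corrected <- c(background = TRUE, normalized = TRUE,
                   acq_bleach = TRUE, depletion = TRUE)

# a fully corrected curve holding given values on the default time base
corrected_curve <- function(F, kind = "DELTA", tb = default_tb) {
  recovery_curve(tb, F, 1, kind = kind, corrections = all_corrected)
}

mono_curve <- function(p, tb = default_tb, noise_sd = 0) {
  F <- mono_exp_model(tb, p)
  if (noise_sd > 0) F <- F + stats::rnorm(length(F), 0, noise_sd)
  corrected_curve(F, "DELTA", tb)
}

bi_curve <- function(p, tb = default_tb, noise_sd = 0) {
  F <- bi_exp_model(tb, p)
  if (noise_sd > 0) F <- F + stats::rnorm(length(F), 0, noise_sd)
  corrected_curve(F, "WHOLE_CELL", tb)
}

# full patterned-cell pipeline from simulated traces to a corrected
# dF curve (control simulated under seed + 5000)
simulate_corrected_delta <- function(gt, seed, n_dots = 7L,
                                     protocol = acquisition_protocol()) {
  sim <- simulate_roi_traces(gt, protocol, n_dots = n_dots, seed = seed)
  ctrl <- simulate_control_series(gt, protocol, seed = seed + 5000L)
  ctrl_curve <- recovery_curve(ctrl$trace$t, ctrl$trace$intensity,
                               ctrl$prebleach, kind = "CONTROL",
                               corrections = c(background = TRUE))
  corrected_delta_curve(curves_from_traces(sim), control = ctrl_curve,
                        depletion = depletion_correction(d = gt$depletion))
}
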