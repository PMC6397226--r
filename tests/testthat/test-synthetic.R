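test_that("the default time base is 50 log-spaced points from 6 ms", {
  tb <- make_timebase(acquisition_protocol())
  expect_equal(tb[1], 0.006)
  expect_length(tb, 50)
  expect_equal(tb[length(tb)], 120)
  expect_true(all(diff(tb) > 0))
  # log-even spacing means constant ratios between consecutive points
  expect_equal(diff(log(tb)), rep(diff(log(tb))[1], 49))
  # tiny geometric example: ratio 10
  tb3 <- make_timebase(acquisition_protocol(n_postbleach_frames = 3,
                                            first_postbleach_delay = 1,
                                            total_duration = 100))
  expect_equal(tb3, c(1, 10, 100))
  expect_error(acquisition_protocol(total_duration = 0.001), "exceed")
})

test_that("noiseless, bleach- and depletion-free dF equals the binding model", {
  gt <- frap_ground_truth(noise_sd = 0, acq_bleach_rate = 0, depletion = 0)
  sim <- simulate_roi_traces(gt, n_dots = 3, seed = 1)
  dots <- curves_from_traces(sim)
  d <- delta_F(dots[[1]]$on, dots[[1]]$off)
  d <- normalize_prebleach(d)
  expect_equal(d$F, mono_exp_model(sim$timebase, gt$binding),
               tolerance = 1e-12)
})

test_that("the binding component makes ON brighter than OFF pre-bleach", {
  gt <- frap_ground_truth(noise_sd = 0)
  sim <- simulate_roi_traces(gt, n_dots = 5, seed = 2)
  expect_true(all(sim$prebleach$on > sim$prebleach$off))
})

test_that("control series carries exactly the per-frame bleach envelope", {
  gt0 <- frap_ground_truth(noise_sd = 0, acq_bleach_rate = 0)
  ctrl0 <- simulate_control_series(gt0, seed = 3)
  expect_equal(ctrl0$trace$intensity, rep(ctrl0$prebleach, 50))
  r <- 0.01
  gtr <- frap_ground_truth(noise_sd = 0, acq_bleach_rate = r)
  ctrl <- simulate_control_series(gtr, seed = 3)
  expect_equal(ctrl$trace$intensity, ctrl$prebleach * (1 - r)^(1:50))
  # dividing a FRAP trace by its paired control removes the envelope
  sim <- simulate_roi_traces(gtr, n_dots = 1, seed = 4)
  ctrl_curve <- recovery_curve(ctrl$trace$t, ctrl$trace$intensity,
                               ctrl$prebleach, kind = "CONTROL",
                               corrections = c(background = TRUE))
  curve <- corrected_delta_curve(curves_from_traces(sim),
                                 control = ctrl_curve,
                                 depletion = depletion_correction(
                                   d = gtr$depletion))
  expect_equal(curve$F, mono_exp_model(sim$timebase, gtr$binding),
               tolerance = 1e-12)
})

test_that("repetitive-bleach series encodes the per-pulse depletion", {
  gt <- frap_ground_truth(noise_sd = 0, depletion = 0.12)
  s <- simulate_repetitive_bleach_series(gt, seed = 5)
  changes <- (s$pulses$pre - s$pulses$post) / s$pulses$pre
  expect_equal(changes[2:5], rep(0.12, 4), tolerance = 1e-12)
  # pulse 1 additionally bleaches slow structures
  expect_gt(changes[1], 0.12)
  gt0 <- frap_ground_truth(noise_sd = 0, depletion = 0)
  s0 <- simulate_repetitive_bleach_series(gt0, first_pulse_extra = 0,
                                          seed = 5)
  expect_equal(s0$pulses$post / s0$pulses$pre, rep(1, 5))
  expect_error(simulate_repetitive_bleach_series(gt, n_pulses = 4, seed = 1),
               "5 pulses")
})

test_that("simulators are deterministic given a seed and require one", {
  gt <- frap_ground_truth()
  expect_identical(simulate_roi_traces(gt, n_dots = 3, seed = 7),
                   simulate_roi_traces(gt, n_dots = 3, seed = 7))
  expect_identical(simulate_calcium_traces(10, 0.5, seed = 7),
                   simulate_calcium_traces(10, 0.5, seed = 7))
  a <- simulate_image_series(frap_ground_truth(),
                             pattern_geometry(n_dots_x = 2, n_dots_y = 2),
                             seed = 7)
  b <- simulate_image_series(frap_ground_truth(),
                             pattern_geometry(n_dots_x = 2, n_dots_y = 2),
                             seed = 7)
  expect_identical(a$frames, b$frames)
  expect_error(simulate_roi_traces(gt, n_dots = 3), "seed")
  expect_error(simulate_control_series(gt), "seed")
  expect_error(simulate_calcium_traces(10, 0.5), "seed")
})

test_that("calcium traces are normalized and match their activation flags", {
  sim <- simulate_calcium_traces(50, 0.5, seed = 8)
  first <- sim$traces$ratio[sim$traces$t == 0]
  expect_equal(first, rep(1, 50))
  res <- percent_activated(sim$traces)
  expect_equal(res$activated, sim$activated)
  # degenerate probabilities classify exactly
  all_on <- simulate_calcium_traces(20, 1, seed = 9)
  expect_equal(percent_activated(all_on$traces)$percent, 100)
  all_off <- simulate_calcium_traces(20, 0, seed = 10)
  expect_equal(percent_activated(all_off$traces)$percent, 0)
})
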