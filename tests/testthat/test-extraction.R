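test_that("ROI traces are background-corrected region means", {
  h <- 20L; w <- 20L
  pre <- matrix(5, h, w); pre[6:10, 6:10] <- 12
  frames <- array(0, dim = c(h, w, 3))
  for (k in 1:3) {
    fr <- matrix(5, h, w); fr[6:10, 6:10] <- 5 + k
    frames[, , k] <- fr
  }
  series <- list(prebleach = pre, frames = frames, timebase = c(1, 2, 3))
  region <- which(matrix(seq_len(h), h, w) %in% 6:10 &
                    matrix(seq_len(w), h, w, byrow = TRUE) %in% 6:10)
  bg <- which(matrix(seq_len(h), h, w) <= 2)
  cv <- extract_roi_trace(series, region, bg)
  expect_equal(cv$prebleach, 7)   # 12 - 5
  expect_equal(cv$F, c(1, 2, 3))  # background removed per frame
  # adding a constant to the whole image leaves the trace unchanged
  series2 <- list(prebleach = pre + 100,
                  frames = frames + 100, timebase = c(1, 2, 3))
  cv2 <- extract_roi_trace(series2, region, bg)
  expect_equal(cv2$F, cv$F)
  expect_error(extract_roi_trace(series, integer(), bg), "empty")
})

test_that("dF subtracts pointwise and preserves the construction", {
  tb <- default_tb
  off <- recovery_curve(tb, rep(0.5, 50), 1, kind = "OFF",
                        corrections = c(background = TRUE))
  on_same <- recovery_curve(tb, rep(0.5, 50), 1, kind = "ON",
                            corrections = c(background = TRUE))
  expect_equal(delta_F(on_same, off)$F, rep(0, 50))
  bind <- mono_exp_model(tb, rep_delta_mono)
  on <- recovery_curve(tb, 0.5 + bind, 2, kind = "ON",
                       corrections = c(background = TRUE))
  d <- delta_F(on, off)
  expect_equal(d$F, bind)
  expect_equal(d$prebleach, 1)
  expect_equal(d$kind, "DELTA")
  short <- recovery_curve(tb[1:10], rep(1, 10), 1, kind = "OFF")
  expect_error(delta_F(on, short), "time base")
})

test_that("pooling is the pointwise mean with the dot count recorded", {
  tb <- default_tb
  mk <- function(v) recovery_curve(tb, rep(v, 50), v, kind = "DELTA")
  pooled <- pool_dots(list(mk(0.2), mk(0.4)))
  expect_equal(pooled$F, rep(0.3, 50))
  expect_equal(pooled$n_dots, 2L)
  expect_equal(pool_dots(list(mk(0.2)))$F, mk(0.2)$F)
  expect_error(pool_dots(list()), "excluded")
})

test_that("pooling reduces noise roughly as one over sqrt(n dots)", {
  gt <- frap_ground_truth(acq_bleach_rate = 0, depletion = 0)
  sds <- vapply(c(1, 9), function(n) {
    resid <- vapply(1:30, function(s) {
      sim <- simulate_roi_traces(gt, n_dots = n, seed = 100 + s)
      dots <- curves_from_traces(sim)
      d <- normalize_prebleach(pool_dots(
        lapply(dots, function(p) delta_F(p$on, p$off))))
      stats::sd(d$F - mono_exp_model(sim$timebase, gt$binding))
    }, numeric(1))
    mean(resid)
  }, numeric(1))
  expect_equal(sds[1] / sds[2], 3, tolerance = 0.25)
})

test_that("pre-bleach normalization scales to 1 and is idempotent", {
  tb <- default_tb
  cv <- recovery_curve(tb, rep(100, 50), 200, kind = "ON")
  n1 <- normalize_prebleach(cv)
  expect_equal(n1$F, rep(0.5, 50))
  expect_equal(n1$prebleach, 1)
  expect_true(n1$corrections[["normalized"]])
  expect_identical(normalize_prebleach(n1), n1)
  dcv <- recovery_curve(tb, rep(10, 50), 50, kind = "DELTA")
  expect_equal(normalize_prebleach(dcv)$F, rep(0.2, 50))
  bad <- recovery_curve(tb, rep(1, 50), 0, kind = "DELTA")
  expect_error(normalize_prebleach(bad), "pre-bleach")
})

test_that("control division removes the bleach envelope exactly", {
  tb <- default_tb
  r <- 0.01
  env <- (1 - r)^(1:50)
  signal <- mono_exp_model(tb, rep_delta_mono)
  cv <- normalize_prebleach(
    recovery_curve(tb, signal * env, 1, kind = "DELTA"))
  ctrl <- recovery_curve(tb, 500 * env, 500, kind = "CONTROL")
  out <- correct_acquisition_bleach(cv, ctrl)
  expect_equal(out$F, signal, tolerance = 1e-12)
  expect_true(out$corrections[["acq_bleach"]])
  # a flat control is the identity
  flat <- recovery_curve(tb, rep(1, 50), 1, kind = "CONTROL",
                         corrections = c(normalized = TRUE))
  expect_equal(correct_acquisition_bleach(cv, flat)$F, cv$F)
  # re-application and zero controls are refused
  expect_error(correct_acquisition_bleach(out, ctrl), "already")
  zero <- recovery_curve(tb, c(0, rep(1, 49)), 1, kind = "CONTROL",
                         corrections = c(normalized = TRUE))
  expect_error(correct_acquisition_bleach(cv, zero), "zero")
  # normalization must come first
  raw <- recovery_curve(tb, signal, 10, kind = "DELTA")
  expect_error(correct_acquisition_bleach(raw, ctrl), "normalize")
})

test_that("depletion correction rescales post-bleach points only", {
  expect_equal(depletion_correction(d = 0.12)$divisor, 0.88)
  expect_equal(depletion_correction(divisor = 0.85)$d, 0.15)
  expect_error(depletion_correction(d = 1.2), "divisor")
  expect_error(depletion_correction(d = 0.1, divisor = 0.9), "exactly one")
  tb <- default_tb
  cv <- normalize_prebleach(
    recovery_curve(tb, rep(0.88, 50), 1, kind = "DELTA"))
  out <- correct_depletion(cv, depletion_correction(d = 0.12))
  expect_equal(out$F, rep(1, 50))
  expect_equal(out$prebleach, 1)  # the pre-bleach point is untouched
  expect_error(correct_depletion(out, depletion_correction(d = 0.12)),
               "already")
  # d = 0 is the identity
  id <- correct_depletion(cv, depletion_correction(d = 0))
  expect_equal(id$F, cv$F)
})

test_that("the full noiseless pipeline reproduces the binding model", {
  gt <- frap_ground_truth(noise_sd = 0)
  curve <- simulate_corrected_delta(gt, seed = 31)
  truth <- mono_exp_model(curve$t, gt$binding)
  expect_lt(max(abs(curve$F - truth)), 1e-6)
  expect_true(all(curve$corrections))
})

test_that("negative dF values from noise are retained, not clipped", {
  gt <- frap_ground_truth(noise_sd = 0.3,
                          binding = mono_exp_params(14.6, 0.3, 0.01))
  curve <- simulate_corrected_delta(gt, seed = 32, n_dots = 1)
  expect_true(any(curve$F < 0))
})
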