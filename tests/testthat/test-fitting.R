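test_that("noiseless mono fits recover the generating parameters", {
  cv <- mono_curve(rep_delta_mono)
  fit <- fit_mono(cv)
  expect_true(fit$converged)
  expect_equal(fit$params$tau, 18.1, tolerance = 1e-6)
  expect_equal(fit$params$f_m, 0.73, tolerance = 1e-6)
  expect_equal(fit$params$b, 0.02, tolerance = 1e-6)
  expect_true(all(is.na(fit$se) | fit$se >= 0))
  expect_gte(fit$n_points, 4)
})

test_that("noiseless bi fits recover every printed parameter set", {
  for (p in list(rep_nonactivated_bi, rep_coated_bi,
                 cohort_nonactivated_bi)) {
    fit <- fit_bi(bi_curve(p))
    expect_true(fit$converged)
    expect_equal(fit$params$tau1, p$tau1, tolerance = 1e-4)
    expect_equal(fit$params$tau2, p$tau2, tolerance = 1e-4)
    expect_equal(fit$params$f_m, p$f_m, tolerance = 1e-4)
    expect_equal(fit$params$b, p$b, tolerance = 1e-4)
    expect_equal(fit$params$c, p$c, tolerance = 1e-4)
    expect_lt(fit$params$tau1, fit$params$tau2)
  }
})

test_that("a single-component curve collapses the bi fit onto the mono fit", {
  p1 <- bi_exp_params(18.1, 1000, 0.73, 0.02, c_frac = 1)
  cv <- corrected_curve(bi_exp_model(default_tb, p1))
  mono <- fit_mono(cv)
  expect_equal(mono$params$tau, 18.1, tolerance = 1e-6)
  expect_equal(mono$params$f_m, 0.73, tolerance = 1e-6)
})

test_that("degenerate constant curves are reported, never silently fit", {
  cv <- corrected_curve(rep(0.5, 50))
  fit <- fit_mono(cv)
  expect_true(!fit$converged || length(fit$flags) > 0)
  if (fit$converged) {
    expect_equal(fit$params$f_m, 0.5, tolerance = 1e-3)
    expect_equal(fit$params$b, 0.5, tolerance = 1e-3)
  }
})

test_that("the bi-exponential residual never exceeds the mono residual", {
  set.seed(41)
  for (i in 1:5) {
    p <- bi_exp_params(runif(1, 0.1, 1), runif(1, 5, 30),
                       runif(1, 0.5, 1), runif(1, 0, 0.4), runif(1))
    cv <- corrected_curve(bi_exp_model(default_tb, p) +
                            rnorm(50, 0, 0.02))
    expect_lte(fit_bi(cv)$rss, fit_mono(cv)$rss + 1e-10)
  }
})

test_that("tau estimates are unbiased within 2 SEM under realistic noise", {
  set.seed(42)
  taus <- vapply(1:60, function(i) {
    fit_mono(mono_curve(rep_delta_mono, noise_sd = 0.02))$params$tau
  }, numeric(1))
  expect_lt(abs(mean(taus) - 18.1), 2 * sd(taus) / sqrt(length(taus)))
})

test_that("tau bias shrinks as noise shrinks", {
  bias <- vapply(c(0.05, 0.01), function(sd) {
    set.seed(43)
    taus <- vapply(1:30, function(i) {
      fit_mono(mono_curve(rep_delta_mono, noise_sd = sd))$params$tau
    }, numeric(1))
    abs(mean(taus) - 18.1)
  }, numeric(1))
  expect_lt(bias[2], bias[1])
  expect_lt(bias[2], 0.1)
})

test_that("poorly separated time constants are flagged, not rejected", {
  p <- bi_exp_params(5, 8, 0.8, 0.1, 0.5)
  fit <- fit_bi(bi_curve(p))
  if (fit$converged && fit$params$tau2 / fit$params$tau1 < 3) {
    expect_true("poorly_separated" %in% fit$flags)
  }
})

test_that("fit_cell dispatches the model by surface type", {
  gt <- frap_ground_truth(noise_sd = 0)
  curve <- simulate_corrected_delta(gt, seed = 44, n_dots = 3)
  rows <- fit_cell(list(delta = curve), surface_type = "patterned",
                   temperature = 22, cell_id = 1, minutes = 10)
  expect_equal(nrow(rows), 1)
  expect_equal(rows$model, "mono")
  expect_equal(rows$kind, "DELTA")
  expect_equal(rows$tau2, 14.6, tolerance = 1e-5)
  wc <- bi_curve(rep_coated_bi)
  rows2 <- fit_cell(list(whole_cell = wc), surface_type = "coated",
                    temperature = 22, cell_id = 2, minutes = 12)
  expect_equal(rows2$model, "bi")
  expect_equal(rows2$kind, "WHOLE_CELL")
  expect_equal(rows2$tau2, 17.0, tolerance = 1e-3)
  # a cell whose required curve is missing is skipped with a message
  expect_message(res <- fit_cell(list(), surface_type = "patterned"),
                 "skipped")
  expect_null(res)
})
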