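test_that("noise-free linear data are reproduced exactly", {
  tt <- seq(0, 240, 12)
  tc <- timecourse(tt, 2 + 0.05 * tt)
  p <- fit_shape_constrained(tc)
  expect_lt(max(abs(predict(p, tt) - tc$values)), 1e-9)
  expect_equal(predict(p, 117, deriv = 1), 0.05, tolerance = 1e-9)
  expect_equal(p$segments, 1)
})

test_that("non-negativity constraint keeps the fitted curve at or above zero", {
  tt <- seq(0, 240, 12)
  vv <- pmax(3 - 0.03 * tt, 0)
  vv[15] <- -0.1
  p <- fit_shape_constrained(timecourse(tt, vv), nonneg = TRUE)
  expect_gte(min(predict(p, seq(0, 240, 0.25))), -1e-10)
})

test_that("noisy logistic data are fit to within the injected noise level", {
  set.seed(42)
  tt <- seq(0, 240, 8)   # 31 points
  truth <- 10 / (1 + exp(-(tt - 100) / 30))
  sigma <- 0.2
  y <- truth + rnorm(length(tt), 0, sigma)
  p <- fit_shape_constrained(timecourse(tt, y))
  expect_lte(p$rms, 2 * sigma)
  expect_lte(p$segments, 4)
})

test_that("fitted profiles are continuously differentiable at the knots", {
  set.seed(7)
  tt <- seq(0, 240, 12)
  y <- 5 + 3 * sin(tt / 60) + rnorm(length(tt), 0, 0.1)
  for (k in 2:4) {
    p <- fit_shape_constrained(timecourse(tt, y), segments = k, nonneg = FALSE)
    knots <- p$t_range[1] + diff(p$t_range) * seq_len(k - 1) / k
    jump <- abs(predict(p, knots + 1e-7, deriv = 1) -
                  predict(p, knots - 1e-7, deriv = 1))
    expect_lt(max(jump), 1e-8)
  }
})

test_that("degenerate inputs are refused with guidance", {
  expect_error(timecourse(c(1, 2, 2, 3), 1:4), "strictly increasing")
  expect_error(fit_shape_constrained(timecourse(1:4, 1:4)), "at least 5")
  expect_error(fit_shape_constrained(timecourse(1:7, 1:7), segments = 3),
               "too few points")
})

test_that("bolus detection flags upward jumps above the threshold", {
  tc <- timecourse(c(0, 12, 24, 36, 48), c(3.9, 2.5, 1.8, 4.0, 3.1), unit = "g/L")
  ev <- detect_boluses(tc, jump_threshold = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$time_before, 24)
  expect_equal(ev$time_after, 36)
  # monotone decreasing series: nothing to flag
  mono <- timecourse(seq(0, 48, 12), seq(5, 1, length.out = 5), unit = "g/L")
  expect_equal(nrow(detect_boluses(mono, 1)), 0)
})

test_that("generator bolus events are recovered from the glucose trace", {
  # sampling must resolve individual refills: at 2-h intervals the
  # consumption between samples stays well below the 2 g/L refill step
  g <- fixture("ref_fine_sampling", function()
    simulate_fedbatch(scenario_preset("REF"), sampling_interval = 2,
                      noise_cv = 0, n_replicates = 1, seed = 1))
  glc <- g$dataset$timecourses$glucose[[1]]
  ev <- detect_boluses(glc, jump_threshold = 1)
  truth <- g$ground_truth$bolus_events
  expect_gt(nrow(truth), 2)
  expect_equal(nrow(ev), nrow(truth))
  # every recorded event lies in a detected jump interval
  for (i in seq_len(nrow(truth)))
    expect_true(any(ev$time_before <= truth$time_h[i] &
                      truth$time_h[i] <= ev$time_after))
})

test_that("log-scale profiles evaluate values and derivatives consistently", {
  tt <- seq(0, 240, 12)
  X <- 7e5 * exp(0.02 * tt)
  p <- fit_log_profile(timecourse(tt, X, unit = "cells/mL"))
  expect_equal(predict(p, 120) / X[tt == 120], 1, tolerance = 1e-6)
  # d/dt exp(f) = exp(f) f'
  expect_equal(predict(p, 120, deriv = 1), 0.02 * predict(p, 120),
               tolerance = 1e-6)
})
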