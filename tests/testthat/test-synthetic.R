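test_that("presets reproduce the calibrated process anchors", {
  ref <- ref_noisefree()$dataset
  expect_equal(max(ref$timecourses$vcd[[1]]$values), 15e6, tolerance = 0.05)
  expect_equal(ref$timecourses$vcd[[1]]$values[1], 0.7e6, tolerance = 0.02)
  cop <- fixture("cop_noisefree", function()
    simulate_fedbatch(scenario_preset("COP"), noise_cv = 0,
                      n_replicates = 1, seed = 1))$dataset
  expect_equal(max(cop$timecourses$vcd[[1]]$values), 9e6, tolerance = 0.05)
  nob <- fixture("nob_noisefree", function()
    simulate_fedbatch(scenario_preset("NOB"), noise_cv = 0,
                      n_replicates = 1, seed = 1))$dataset
  expect_equal(max(nob$timecourses$vcd[[1]]$values), 13e6, tolerance = 0.05)
  # base-free phenotype: lactate plateaus at a low level, titer is highest
  lac <- nob$timecourses$lactate[[1]]
  plateau <- lac$values[lac$times >= 120 & lac$times <= 216]
  expect_equal(mean(plateau), 25, tolerance = 0.15)
  expect_lt(max(lac$values), 32)
  expect_equal(tail(nob$timecourses$mab[[1]]$values, 1), 1.6, tolerance = 0.1)
  expect_gt(tail(nob$timecourses$mab[[1]]$values, 1),
            tail(ref$timecourses$mab[[1]]$values, 1))
})

test_that("ground-truth productivity trajectories carry the printed peaks", {
  ref <- scenario_preset("REF")
  tgrid <- seq(0, 264, 0.5)
  q <- ref$q_mab(tgrid)
  expect_equal(max(q), 18, tolerance = 0.01)
  expect_equal(tgrid[which.max(q)], 120, tolerance = 12)
  cop <- scenario_preset("COP")
  expect_equal(max(cop$q_mab(tgrid)), 23, tolerance = 0.01)
  expect_lt(tgrid[which.max(cop$q_mab(tgrid))], 40)
  nob <- scenario_preset("NOB")
  expect_equal(max(nob$q_mab(tgrid)), 20, tolerance = 0.01)
  expect_gt(tgrid[which.max(nob$q_mab(tgrid))], 220)
  # lactate consumption switch inside the printed window
  qlac <- nob$q_lac(tgrid)
  sw <- tgrid[which(qlac < 0)[1]]
  expect_gt(sw, 144); expect_lt(sw, 240)
  # declining growth in the CO2-stressed process across phases 2-4
  mus <- cop$mu(c(82, 154, 238))
  expect_true(all(diff(mus) < 0))
})

test_that("the glucose bolus rule keeps the concentration band", {
  g <- ref_noisefree()
  glc <- g$dataset$timecourses$glucose[[1]]$values
  expect_gt(min(glc), 1.7)    # refills engage near 2 g/L
  ev <- g$ground_truth$bolus_events
  expect_gt(nrow(ev), 2)
  expect_true(all(ev$amount > 0))
})

test_that("generation is deterministic and noise behaves as configured", {
  a <- simulate_fedbatch(scenario_preset("REF"), noise_cv = 0.03,
                         n_replicates = 2, seed = 9)
  b <- simulate_fedbatch(scenario_preset("REF"), noise_cv = 0.03,
                         n_replicates = 2, seed = 9)
  expect_identical(a$dataset$timecourses$vcd[[1]]$values,
                   b$dataset$timecourses$vcd[[1]]$values)
  expect_identical(a$dataset$pools, b$dataset$pools)
  # noise-free: replicates identical; noisy: they differ and stay positive
  nf <- ref_noisefree()
  expect_false(identical(a$dataset$timecourses$vcd[[1]]$values,
                         a$dataset$timecourses$vcd[[2]]$values))
  expect_true(all(a$dataset$timecourses$lactate[[1]]$values >= 0))
  cv_obs <- sd(a$dataset$timecourses$vcd[[1]]$values /
                 nf$dataset$timecourses$vcd[[1]]$values)
  expect_equal(cv_obs, 0.03, tolerance = 0.5)
})

test_that("custom scenarios pass user trajectories through unchanged", {
  anchors <- chofba:::scenario_anchor_sets()$REF
  anchors$q_mab <- list(t = c(0, 264), v = c(5, 5))
  sc <- scenario_preset("custom", custom = anchors)
  expect_equal(sc$q_mab(123), 5, tolerance = 1e-9)
  expect_error(scenario_preset("FOO"), "arg")
  expect_error(scenario_preset("custom"), "custom")
})

test_that("phase pools are emitted for the four sampling times", {
  g <- ref_noisefree()
  pools <- g$dataset$pools
  expect_setequal(unique(pools$time_h), c(33, 82, 154, 238))
  expect_true(all(pools[, c("amp", "adp", "atp", "pyr")] > 0))
})
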