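test_that("a constant concentration in a batch gives a zero rate", {
  tt <- seq(0, 240, 12)
  feed <- feed_program(feed_rate = 0)
  pC <- fit_shape_constrained(timecourse(tt, rep(4, length(tt))))
  pX <- fit_shape_constrained(timecourse(tt, rep(1e6, length(tt)), unit = "cells/mL"))
  expect_equal(specific_rate(pC, pX, feed, 100), 0, tolerance = 1e-9)
})

test_that("a hand-computed titer balance gives 10 pg/cell/day", {
  # X = 1e6 cells/mL, dP/dt = 10 mg/L/day, no feed:
  # 0.01 g/L/day over 1e9 cells/L = 1e-11 g/cell/day = 10 pg/cell/day
  tt <- seq(0, 240, 12)
  feed <- feed_program(feed_rate = 0)
  pP <- fit_shape_constrained(timecourse(tt, 0.01 * tt / 24, unit = "g/L"))
  pX <- fit_shape_constrained(timecourse(tt, rep(1e6, length(tt)), unit = "cells/mL"))
  expect_equal(specific_rate_mab(pP, pX, feed, 120), 10, tolerance = 1e-6)
})

test_that("growth rate recovers exponential growth and dilution balance", {
  tt <- seq(0, 240, 12)
  feed0 <- feed_program(feed_rate = 0)
  X <- 7e5 * exp(0.5 * tt / 24)   # mu = 0.5/day
  pX <- fit_log_profile(timecourse(tt, X, unit = "cells/mL"))
  expect_equal(growth_rate(pX, feed0, 120), 0.5, tolerance = 0.005)
  # stationary culture under dilution: mu equals D exactly
  feedD <- feed_program(feed_rate = 0.05, feed_start = 0)
  pXc <- fit_shape_constrained(timecourse(tt, rep(5e6, length(tt)), unit = "cells/mL"))
  D <- 0.05 / (1 + 0.05 * 120 / 24)
  expect_equal(growth_rate(pXc, feedD, 120), D, tolerance = 1e-9)
})

test_that("replicate combination uses the mean and sample SD", {
  tabs <- lapply(c(10, 12, 14), function(v) rate_table("glucose", v, 0, 82))
  comb <- rate_errors_from_replicates(tabs)
  expect_equal(comb$value, 12)
  expect_equal(comb$error, 2)
  ident <- rate_errors_from_replicates(lapply(1:3, function(i)
    rate_table("glucose", 7, 0, 82)))
  expect_equal(ident$error, 0)
  expect_warning(single <- rate_errors_from_replicates(list(tabs[[1]])),
                 "single replicate")
  expect_equal(single$error, 0)
})

test_that("noise-free rates are recovered within 2% away from the edges", {
  g <- ref_noisefree()
  est <- ref_noisefree_rates()
  for (tp in c("t82", "t154")) {
    truth <- g$ground_truth$rate_tables[[tp]]
    mm <- merge(truth, est[[tp]], by = "quantity")
    big <- abs(mm$value.x) > 50 | mm$quantity %in% c("mu", "mab")
    rel <- abs(mm$value.y - mm$value.x) / abs(mm$value.x)
    expect_lt(max(rel[big]), 0.03)
  }
})

test_that("NOB rates switch from lactate production to consumption", {
  g <- fixture("nob_noisefree", function()
    simulate_fedbatch(scenario_preset("NOB"), noise_cv = 0,
                      n_replicates = 1, seed = 1))
  est <- estimate_rates(g$dataset)
  expect_gt(est$t82$value[est$t82$quantity == "lactate"], 0)
  expect_lt(est$t238$value[est$t238$quantity == "lactate"], 0)
})

test_that("carbon closure bookkeeping matches hand examples", {
  m <- core_model()
  carbon <- carbon_counts(m)
  # all glucose carbon to lactate at yield 2 mol/mol closes exactly
  rt <- rate_table(c("glucose", "lactate"), c(-1, 2), 0)
  cb <- carbon_balance(rt, carbon, m)
  expect_equal(cb$closure, 1)
  expect_identical(cb$unmeasured_sinks, "co2")
  # the generator's ground-truth rate set (with CO2) is carbon closed
  g <- ref_noisefree()
  cb2 <- carbon_balance(g$ground_truth$rate_tables$t82, carbon, m)
  expect_equal(cb2$closure, 1, tolerance = 0.02)
  expect_length(cb2$unmeasured_sinks, 0)
  # dropping CO2 leaves a deficit and names the sink
  rt3 <- g$ground_truth$rate_tables$t82
  cb3 <- carbon_balance(rt3[rt3$quantity != "co2", ], carbon, m)
  expect_lt(cb3$closure, 1)
  expect_identical(cb3$unmeasured_sinks, "co2")
  expect_error(carbon_balance(rate_table("unknown_thing", -5, 0), carbon, m),
               "missing carbon")
})

test_that("culture datasets survive the long-format CSV round trip", {
  g <- ref_noisefree()
  f <- withr::local_tempfile(fileext = ".csv")
  write_culture_csv(g$dataset, f)
  df <- read_culture_csv(f)
  expect_setequal(unique(df$analyte), names(g$dataset$timecourses))
  glc <- df[df$analyte == "glucose" & df$replicate == 1, ]
  expect_equal(glc$value, g$dataset$timecourses$glucose[[1]]$values)
  expect_identical(unique(glc$unit), "g/L")
})
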