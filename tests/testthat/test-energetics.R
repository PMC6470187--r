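test_that("the ATP ledger decomposes full glucose oxidation as 28/2/2", {
  m <- core_model()
  sol <- solve_max_atp(constrain_exchanges(m, desk_rates(glucose = -1)))
  led <- atp_ledger(sol, m)
  expect_equal(led$q_atp_total, 32, tolerance = 1e-6)
  expect_equal(unname(led$contributions["oxphos_nadh"]), 25, tolerance = 1e-6)
  expect_equal(unname(led$contributions["oxphos_fadh2"]), 3, tolerance = 1e-6)
  expect_equal(unname(led$contributions["slp_glycolysis"]), 2, tolerance = 1e-6)
  expect_equal(unname(led$contributions["scs"]), 2, tolerance = 1e-6)
  expect_equal(unname(led$fractions["oxphos_nadh"]), 25 / 32, tolerance = 1e-6)
})

test_that("the lactate-only route is pure glycolytic SLP", {
  m <- core_model()
  sol <- solve_max_atp(constrain_exchanges(m, desk_rates(glucose = -1,
                                                         lactate = 2)))
  led <- atp_ledger(sol, m)
  expect_equal(led$q_atp_total, 2, tolerance = 1e-6)
  expect_equal(unname(led$fractions["slp_glycolysis"]), 1, tolerance = 1e-6)
})

test_that("ledger conservation holds, including the zero-flux state", {
  m <- core_model()
  sol0 <- solve_max_atp(constrain_exchanges(m, desk_rates()))
  led0 <- atp_ledger(sol0, m)
  expect_equal(led0$q_atp_total, 0, tolerance = 1e-9)
  expect_equal(max(abs(led0$contributions)), 0, tolerance = 1e-9)
  res <- ref_noisefree_pipeline()
  for (p in res$phases) {
    led <- p$ledger
    expect_equal(sum(led$contributions), led$q_atp_total,
                 tolerance = 1e-6 * max(1, abs(led$q_atp_total)))
    expect_equal(sum(led$fractions), 1, tolerance = 1e-6)
  }
})

test_that("ATP yield per c-mol matches hand arithmetic and its guards", {
  m <- core_model()
  carbon <- carbon_counts(m)
  sol <- solve_max_atp(constrain_exchanges(m, desk_rates(glucose = -1)))
  led <- atp_ledger(sol, m)
  expect_equal(atp_yield_per_cmol(led, rate_table("glucose", -1, 0), carbon),
               32 / 6, tolerance = 1e-6)
  sol2 <- solve_max_atp(constrain_exchanges(m, desk_rates(glucose = -1, lactate = 2)))
  led2 <- atp_ledger(sol2, m)
  # produced lactate must not count as consumed carbon
  rt2 <- rate_table(c("glucose", "lactate"), c(-1, 2), 0)
  expect_equal(atp_yield_per_cmol(led2, rt2, carbon), 2 / 6, tolerance = 1e-6)
  expect_error(atp_yield_per_cmol(led, rate_table("glucose", 0, 0), carbon),
               "consumed")
})

test_that("Y_ATP,C scales inversely with consumption at fixed ATP", {
  m <- core_model()
  carbon <- carbon_counts(m)
  led <- atp_ledger(solve_max_atp(constrain_exchanges(m, desk_rates(glucose = -1))), m)
  y1 <- atp_yield_per_cmol(led, rate_table("glucose", -1, 0), carbon)
  y3 <- atp_yield_per_cmol(led, rate_table("glucose", -3, 0), carbon)
  expect_equal(y3, y1 / 3, tolerance = 1e-9)
})

test_that("adenylate energy charge follows the Atkinson definition", {
  expect_equal(adenylate_energy_charge(list(amp = 0.2, adp = 0.8, atp = 4.0)),
               0.88, tolerance = 1e-9)
  expect_equal(adenylate_energy_charge(list(amp = 0, adp = 0, atp = 3)), 1)
  expect_equal(adenylate_energy_charge(list(amp = 1, adp = 0, atp = 0)), 0)
  expect_error(adenylate_energy_charge(list(amp = 0, adp = 0, atp = 0)), "zero")
  expect_error(adenylate_energy_charge(list(amp = -1, adp = 1, atp = 1)),
               "non-negative")
})

test_that("AEC is bounded and monotone in its pools", {
  set.seed(3)
  for (i in 1:50) {
    pools <- list(amp = runif(1, 0, 5), adp = runif(1, 0, 5), atp = runif(1, 0, 5))
    aec <- adenylate_energy_charge(pools)
    expect_gte(aec, 0); expect_lte(aec, 1)
    up <- pools; up$atp <- up$atp + 0.5
    expect_gt(adenylate_energy_charge(up), aec - 1e-12)
    down <- pools; down$amp <- down$amp + 0.5
    expect_lt(adenylate_energy_charge(down), aec + 1e-12)
  }
})
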