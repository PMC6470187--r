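test_that("measured rates translate into exchange bounds", {
  m <- core_model()
  pr <- constrain_exchanges(m, desk_rates(glucose = c(-900, 50),
                                          lactate = c(500, 0)))
  expect_equal(unname(pr$lb["EX_glc"]), -950)
  expect_equal(unname(pr$ub["EX_glc"]), -850)
  expect_equal(unname(pr$lb["EX_lac"]), 500)
  expect_equal(unname(pr$ub["EX_lac"]), 500)
  expect_error(constrain_exchanges(m, rate_table("nonexistent", 1, 0)),
               "nonexistent")
  # growth and antibody rates map onto the pseudo-fluxes
  pr2 <- constrain_exchanges(m, desk_rates(mu = c(0.5, 0.01), mab = c(15, 1.5)))
  expect_equal(unname(pr2$lb["BIOMASS"]), 0.49)
  expect_equal(unname(pr2$ub["MAB"]), 16.5 / 150, tolerance = 1e-12)
})

test_that("complete glucose oxidation yields 32 ATP at the drain", {
  sol <- solve_max_atp(constrain_exchanges(core_model(), desk_rates(glucose = -1)))
  # 2 glycolytic SLP + 2.5*10 NADH + 1.5*2 FADH2 + 2 GTP
  expect_equal(sol$objective, 32, tolerance = 1e-6)
  expect_lt(max(abs(sol$problem$S %*% sol$flux)), 1e-6)
  expect_true(all(sol$flux >= sol$problem$lb - 1e-9))
  expect_true(all(sol$flux <= sol$problem$ub + 1e-9))
})

test_that("the glycolysis-to-lactate route yields 2 ATP", {
  sol <- solve_max_atp(constrain_exchanges(core_model(),
                                           desk_rates(glucose = -1, lactate = 2)))
  expect_equal(sol$objective, 2, tolerance = 1e-6)
  expect_equal(unname(sol$flux["LDH"]), 2, tolerance = 1e-6)
})

test_that("closing every exchange forces the zero flux state", {
  sol <- solve_max_atp(constrain_exchanges(core_model(), desk_rates()))
  expect_equal(sol$objective, 0, tolerance = 1e-9)
  expect_lt(max(abs(sol$flux)), 1e-6)
})

test_that("node conservation pins LDH and ALT to the printed secretions", {
  m <- core_model()
  # early-stationary lactate secretion of the CO2-stressed process
  s3 <- solve_max_atp(constrain_exchanges(m, desk_rates(glucose = c(-2500, 2500),
                                                        lactate = 1200)))
  expect_equal(unname(s3$flux["LDH"]), 1200, tolerance = 1e-6)
  # growth-phase alanine secretion with growth and antibody silenced
  s4 <- solve_max_atp(constrain_exchanges(m, desk_rates(glucose = c(-2500, 2500),
                                                        ala = 200)))
  expect_equal(unname(s4$flux["ALT"]), 200, tolerance = 1e-6)
  # growth-phase lactate secretion
  s5 <- solve_max_atp(constrain_exchanges(m, desk_rates(glucose = c(-2500, 2500),
                                                        lactate = 500)))
  expect_equal(unname(s5$flux["LDH"]), 500, tolerance = 1e-6)
})

test_that("flux variability brackets the optimum and respects fixing", {
  m <- core_model()
  pr <- constrain_exchanges(m, desk_rates(glucose = c(-2500, 2500), lactate = 500))
  expect_equal(unname(flux_variability(pr, "LDH")), c(500, 500), tolerance = 1e-6)
  fv <- flux_variability(pr, "PDH")
  expect_lte(fv["min"], fv["max"])
  # with the objective forced to optimality the drain range collapses upward
  opt <- solve_max_atp(pr)$objective
  fv_opt <- flux_variability(pr, "ATP_DRAIN", optimality_fraction = 1)
  expect_equal(unname(fv_opt["min"]), opt, tolerance = 1e-4 * abs(opt))
})

test_that("the LP is invariant to row and column permutations", {
  m <- core_model()
  rt <- desk_rates(glucose = c(-1000, 50), lactate = c(1200, 100),
                   gln = c(-100, 10), ala = c(150, 20))
  pr <- constrain_exchanges(m, rt)
  base <- solve_max_atp(pr)$objective
  set.seed(1)
  for (i in 1:3) {
    pr2 <- pr
    pi_r <- sample(nrow(pr$S))
    pi_c <- sample(ncol(pr$S))
    pr2$S <- pr$S[pi_r, pi_c]
    pr2$lb <- pr$lb[pi_c]; pr2$ub <- pr$ub[pi_c]
    pr2$objective <- pr$objective[pi_c]
    res <- chofba:::solve_lp(pr2$objective, pr2$S, pr2$lb, pr2$ub, maximize = TRUE)
    expect_equal(res$objective, base, tolerance = 1e-6 * abs(base))
  }
})

test_that("the optimum is homogeneous and monotone in the bounds", {
  m <- core_model()
  rt <- desk_rates(glucose = c(-1000, 50), lactate = c(1200, 100),
                   gln = c(-100, 10), ala = c(150, 20))
  pr <- constrain_exchanges(m, rt)
  base <- solve_max_atp(pr)$objective
  for (k in c(0.5, 2)) {
    rk <- rt
    rk$value <- rt$value * k
    rk$error <- rt$error * k
    sk <- solve_max_atp(constrain_exchanges(m, rk))
    expect_equal(sk$objective, k * base, tolerance = 1e-6 * abs(k * base))
  }
  # tightening the glucose bound can never raise the optimum
  tighter <- rt
  tighter$error[tighter$quantity == "glucose"] <- 10
  expect_lte(solve_max_atp(constrain_exchanges(m, tighter))$objective,
             base + 1e-6)
  # random toy instances: shrinking a box never helps
  set.seed(9)
  for (i in 1:5) {
    n <- 6
    S <- matrix(sample(-1:1, 2 * n, TRUE), 2, n,
                dimnames = list(NULL, paste0("r", 1:n)))
    lb <- runif(n, -5, -1); ub <- runif(n, 1, 5)
    obj <- rnorm(n)
    a <- chofba:::solve_lp(obj, S, lb, ub, TRUE)
    j <- sample(n, 1)
    b <- chofba:::solve_lp(obj, S, lb, ub * replace(rep(1, n), j, 0.5), TRUE)
    if (a$status == "optimal" && b$status == "optimal")
      expect_lte(b$objective, a$objective + 1e-8)
  }
})

test_that("infeasible measured bounds produce an elastic relaxation diagnosis", {
  m <- core_model()
  # forced cysteine secretion has no internal source
  err <- tryCatch(solve_max_atp(constrain_exchanges(m, desk_rates(cys = 50))),
                  error = identity)
  expect_s3_class(err, "chofba_infeasible")
  relax <- err$relaxation
  expect_gt(relax[["EX_cys"]], 0)
  expect_true(all(relax[names(relax) != "EX_cys"] < 50))
})
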