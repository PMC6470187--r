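test_that("a single free reaction is sampled uniformly on its interval", {
  # r1 - r2 = 0 with both in [0, 1]: one free dimension, uniform on [0,1]
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("r1", "r2")))
  pr <- toy_problem(S, c(0, 0), c(1, 1))
  sm <- sample_fluxes(pr, 2000, 10, seed = 42)
  se <- 1 / sqrt(12) / sqrt(200)   # conservative: treat chains as independent
  expect_lt(abs(mean(sm$points[, "r1"]) - 0.5), 3 * max(se, 0.02))
  expect_equal(sd(sm$points[, "r1"]), 1 / sqrt(12), tolerance = 0.1)
})

test_that("hit-and-run agrees with the rejection oracle on small polytopes", {
  # v1 + v2 = 1 (uniform on the 1-simplex)
  S1 <- matrix(c(1, -1, -1), 1, 3, dimnames = list("A", c("src", "v1", "v2")))
  pr1 <- toy_problem(S1, c(1, 0, 0), c(1, 5, 5))
  hr <- sample_fluxes(pr1, 3000, 10, seed = 1)
  or <- rejection_oracle(pr1, 3000, seed = 2)
  for (v in c("v1", "v2")) {
    se <- sqrt(1 / 12) / sqrt(300)
    expect_lt(abs(mean(hr$points[, v]) - mean(or$points[, v])), 3 * max(se, 0.02))
    expect_equal(sd(hr$points[, v]), sd(or$points[, v]), tolerance = 0.15)
  }
  # a 2-simplex: v1 + v2 + v3 = 1
  S2 <- matrix(c(1, -1, -1, -1), 1, 4,
               dimnames = list("A", c("src", "v1", "v2", "v3")))
  pr2 <- toy_problem(S2, c(1, 0, 0, 0), c(1, 5, 5, 5))
  hr2 <- sample_fluxes(pr2, 3000, 10, seed = 3)
  or2 <- rejection_oracle(pr2, 3000, seed = 4)
  expect_lt(abs(mean(hr2$points[, "v1"]) - mean(or2$points[, "v1"])), 0.05)
})

test_that("every emitted sample is feasible", {
  g <- ref_noisefree_pipeline()
  pr <- g$phases$t82$problem
  sm <- sample_fluxes(pr, 400, 4, seed = 11, warmup = 200)
  idx <- sample(nrow(sm$points), 40)
  resid <- abs(pr$S %*% t(sm$points[idx, ]))
  expect_lt(max(resid), 1e-6 * max(1, max(abs(sm$points[idx, ]))))
  expect_true(all(t(sm$points[idx, ]) >= pr$lb - 1e-6))
  expect_true(all(t(sm$points[idx, ]) <= pr$ub + 1e-6))
})

test_that("a fixed seed reproduces the sample stream bit-identically", {
  S <- matrix(c(1, -1, -1), 1, 3, dimnames = list("A", c("src", "v1", "v2")))
  pr <- toy_problem(S, c(1, 0, 0), c(1, 5, 5))
  a <- sample_fluxes(pr, 500, 5, seed = 7)
  b <- sample_fluxes(pr, 500, 5, seed = 7)
  expect_identical(a$points, b$points)
  c <- sample_fluxes(pr, 500, 5, seed = 8)
  expect_false(identical(a$points, c$points))
})

test_that("a fully fixed polytope collapses to its single point", {
  S <- matrix(c(1, -1, -1), 1, 3, dimnames = list("A", c("src", "v1", "v2")))
  pr <- toy_problem(S, c(1, 0.4, 0.6), c(1, 0.4, 0.6))
  sm <- sample_fluxes(pr, 50, 4, seed = 3)
  expect_equal(max(apply(sm$points, 2, sd)), 0)
  expect_equal(unname(sm$points[1, ]), c(1, 0.4, 0.6))
  or <- rejection_oracle(pr, 20, seed = 1)
  expect_equal(unname(or$points[5, ]), c(1, 0.4, 0.6))
})

test_that("flux statistics summarize the cloud per reaction", {
  S <- matrix(c(1, -1), 1, 2, dimnames = list("A", c("r1", "r2")))
  pr <- toy_problem(S, c(0, 0), c(1, 1))
  sm <- sample_fluxes(pr, 2000, 10, seed = 5)
  fs <- flux_statistics(sm)
  expect_named(fs, c("reaction", "mean", "sd", "q2.5", "q97.5"))
  # box marginal: sd ~ range/sqrt(12)
  expect_equal(fs$sd[fs$reaction == "r1"], 1 / sqrt(12), tolerance = 0.12)
  expect_lt(fs$q2.5[1], fs$q97.5[1])
  # constant samples have zero spread
  cst <- sm; cst$points[] <- 1
  expect_equal(max(flux_statistics(cst)$sd), 0)
  # sample means satisfy the steady state by linearity
  expect_lt(max(abs(S %*% flux_statistics(sm)$mean)), 1e-9)
})

test_that("the rejection oracle guards its applicability", {
  # a 5-dimensional simplex exceeds the oracle's dimension guard
  S <- matrix(c(1, rep(-1, 6)), 1, 7,
              dimnames = list("A", c("src", paste0("v", 1:6))))
  pr <- toy_problem(S, c(1, rep(0, 6)), c(1, rep(5, 6)))
  expect_error(rejection_oracle(pr, 10, seed = 1), "free dimensions")
})
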