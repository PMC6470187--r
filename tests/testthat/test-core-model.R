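test_that("core model satisfies its structural invariants", {
  m <- core_model()
  carbon <- carbon_counts(m)
  # every internal reaction is carbon balanced
  for (r in m$reactions) {
    if (r$tag %in% c("exchange", "biomass", "mab_synthesis")) next
    expect_equal(carbon_balance_check(r, carbon), 0,
                 info = paste("carbon residual of", r$id))
  }
  # unique roles
  expect_length(reactions_by_tag(m, "atp_drain"), 1)
  expect_length(reactions_by_tag(m, "biomass"), 1)
  expect_length(reactions_by_tag(m, "mab_synthesis"), 1)
  # lactate node: LDH is the only internal lactate reaction
  internal <- Filter(function(r) !r$tag %in% c("transport", "exchange"),
                     m$reactions)
  touches_lac <- Filter(function(r) "lac" %in% names(r$stoichiometry), internal)
  expect_identical(vapply(touches_lac, `[[`, "", "id"), c(LDH = "LDH"))
  # alanine's only internal carbon source is the transaminase (plus
  # biomass/antibody drains, which only consume)
  touches_ala <- Filter(function(r) "ala" %in% names(r$stoichiometry), internal)
  producers <- Filter(function(r) r$stoichiometry[["ala"]] > 0 || r$reversible,
                      touches_ala)
  expect_identical(vapply(producers, `[[`, "", "id"), c(ALT = "ALT"))
})

test_that("oxidative phosphorylation carries the configured P/O ratios", {
  m <- core_model()
  expect_equal(m$reactions$OXPHOS_NADH$stoichiometry[["atp"]], 2.5)
  expect_equal(m$reactions$OXPHOS_FADH2$stoichiometry[["atp"]], 1.5)
  m1 <- build_core_model(po_nadh = 1.0)
  expect_equal(m1$reactions$OXPHOS_NADH$stoichiometry[["atp"]], 1.0)
  expect_equal(m1$reactions$OXPHOS_NADH$stoichiometry[["adp"]], -1.0)
  expect_error(build_core_model(po_nadh = -1), "P/O")
  expect_error(build_core_model(biomass_composition = numeric()), "biomass")
})

test_that("exchange reactions are complete, unique and idempotent", {
  m <- core_model()
  extra <- names(m$metabolites)[
    vapply(m$metabolites, `[[`, "", "compartment") == "extracellular"]
  ex_rxns <- m$reactions[reactions_by_tag(m, "exchange")]
  exchanged <- vapply(ex_rxns, function(r) names(r$stoichiometry), "")
  expect_setequal(exchanged, extra)
  expect_false(anyDuplicated(exchanged) > 0)
  m2 <- add_exchange_reactions(m)
  expect_equal(length(m2$reactions), length(m$reactions))
})

test_that("the stoichiometric matrix reflects reaction coefficients", {
  mets <- list(metabolite("A", carbon_count = 0),
               metabolite("B", carbon_count = 0),
               metabolite("B_e", compartment = "extracellular", carbon_count = 0))
  rxns <- list(
    reaction("conv", c(A = -1, B = 1), tag = "transport"),
    reaction("exp", c(B = -1, B_e = 1), tag = "transport"),
    reaction("EX_A_in", c(A = 1), tag = "biomass"),   # pseudo source
    reaction("drain", c(A = -1), tag = "atp_drain"),
    reaction("mabish", c(B = -1), tag = "mab_synthesis"),
    reaction("EX_B", c(B_e = -1), reversible = TRUE, tag = "exchange"))
  m <- network_model(mets, rxns)
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(3, 6))
  expect_equal(unname(S[, "conv"]), c(-1, 1, 0))
  expect_equal(as.numeric(S %*% numeric(6)), numeric(3))
  # full model dimensions
  Sm <- stoichiometric_matrix(core_model())
  expect_equal(dim(Sm), c(length(core_model()$metabolites),
                          length(core_model()$reactions)))
})

test_that("carbon residuals are computed and guarded", {
  carbon <- c(glc = 6, lac = 3, pyr = 3)
  ldh <- reaction("ldh", c(pyr = -1, lac = 1), tag = "glycolysis")
  expect_equal(carbon_balance_check(ldh, carbon), 0)
  # hypothetical glucose -> 1 lactate loses three carbons
  bad <- reaction("bad", c(glc = -1, lac = 1), tag = "glycolysis")
  expect_equal(carbon_balance_check(bad, carbon), -3)
  expect_error(carbon_balance_check(reaction("x", c(unknown = 1), tag = "exchange"),
                                    carbon), "unknown")
  # exchange reactions carry a nonzero residual but pass model validation
  m <- core_model()
  expect_equal(carbon_balance_check(m$reactions$EX_glc, carbon_counts(m)), -6)
})

test_that("the reaction registry exports as JSON", {
  js <- write_reaction_registry(core_model())
  reg <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  expect_equal(length(reg), length(core_model()$reactions))
  ids <- vapply(reg, `[[`, "", "id")
  expect_true(all(c("LDH", "ALT", "ATP_DRAIN", "BIOMASS") %in% ids))
})
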