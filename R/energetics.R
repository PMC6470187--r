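# Cellular energetics: ATP ledgers, yields per c-mol, adenylate energy charge.

#' Decompose ATP production by source
#'
#' Splits the gross cellular ATP production of a flux solution into its
#' four sources: oxidative phosphorylation of NADH (P/O ratio times the
#' NADH-oxphos flux), oxidative phosphorylation of FADH2, net glycolytic
#' substrate-level phosphorylation (ATP formed by phosphoglycerate kinase
#' and pyruvate kinase minus ATP invested by hexokinase and
#' phosphofructokinase), and succinyl-CoA synthetase in the TCA cycle.
#'
#' @param solution a `chofba_flux_solution`.
#' @param model the `chofba_model` the solution was computed on.
#' @return A `chofba_atp_ledger`: list with `q_atp_total` (fmol/cell/day),
#'   `contributions` (named vector, same unit) and `fractions`
#'   (dimensionless, summing to 1 when total > 0).
#' @export
atp_ledger <- function(solution, model) {
  flux <- solution$flux
  oxphos <- reactions_by_tag(model, "oxphos")
  nadh_rxn <- oxphos[vapply(model$reactions[oxphos],
                            function(r) "nadh" %in% names(r$stoichiometry), NA)]
  fadh_rxn <- setdiff(oxphos, nadh_rxn)
  atp_coeff <- function(rid) {
    st <- model$reactions[[rid]]$stoichiometry
    if ("atp" %in% names(st)) st[["atp"]] else 0
  }
  contr <- c(
    oxphos_nadh = sum(vapply(nadh_rxn, function(r) atp_coeff(r) * flux[[r]], 0)),
    oxphos_fadh2 = sum(vapply(fadh_rxn, function(r) atp_coeff(r) * flux[[r]], 0)),
    slp_glycolysis = sum(vapply(reactions_by_tag(model, "glycolysis"),
                                function(r) atp_coeff(r) * flux[[r]], 0)),
    scs = sum(vapply(reactions_by_tag(model, "tca"),
                     function(r) max(atp_coeff(r), 0) * flux[[r]], 0))
  )
  total <- sum(contr)
  fractions <- if (abs(total) > 0) contr / total else contr * 0
  structure(list(q_atp_total = total, contributions = contr,
                 fractions = fractions),
            class = "chofba_atp_ledger")
}

#' @export
print.chofba_atp_ledger <- function(x, ...) {
  cat(sprintf("ATP production ledger: q_ATP = %.4g fmol/cell/day (%.3g pmol/cell/day)\n",
              x$q_atp_total, x$q_atp_total / 1000))
  for (k in names(x$contributions))
    cat(sprintf("  %-15s %10.4g  (%5.1f%%)\n", k, x$contributions[[k]],
                100 * x$fractions[[k]]))
  invisible(x)
}

#' ATP yield per c-mol of consumed substrate
#'
#' `Y_ATP,C = q_ATP_total / sum(|rate| * carbon_count)` over net-consumed
#' carbon substrates only: glucose, amino acids with negative (uptake)
#' rates, and lactate when it is consumed, never when it is produced.
#'
#' @param ledger a `chofba_atp_ledger`.
#' @param rates rate table (data frame with `quantity`, `value`) in
#'   fmol/cell/day for metabolite rates; `mu` and `mab` entries are
#'   ignored here.
#' @param carbon_registry named vector, substrate id -> carbon atoms per
#'   molecule. Quantities named `glucose` and `lactate` map to ids `glc`
#'   and `lac`.
#' @return Y_ATP,C in mol ATP per c-mol.
#' @export
atp_yield_per_cmol <- function(ledger, rates, carbon_registry) {
  met <- rates[!rates$quantity %in% c("mu", "mab"), , drop = FALSE]
  consumed <- met[met$value < 0, , drop = FALSE]
  assert_that(nrow(consumed) > 0, "no net-consumed carbon substrate in rate table")
  ids <- ifelse(consumed$quantity == "glucose", "glc",
                ifelse(consumed$quantity == "lactate", "lac", consumed$quantity))
  missing <- setdiff(ids, names(carbon_registry))
  assert_that(length(missing) == 0, "no carbon count for: %s",
              paste(missing, collapse = ", "))
  cmol_in <- sum(abs(consumed$value) * carbon_registry[ids])
  assert_that(cmol_in > 0, "zero consumed carbon: Y_ATP,C undefined")
  ledger$q_atp_total / cmol_in
}

#' Adenylate energy charge
#'
#' Atkinson's charge `(ATP + ADP/2) / (AMP + ADP + ATP)`, a 0-1 index of
#' the cellular energy state.
#'
#' @param pools named list or vector with elements `amp`, `adp`, `atp`
#'   (fmol/cell, any common unit).
#' @return AEC in \[0, 1\].
#' @export
adenylate_energy_charge <- function(pools) {
  amp <- pools[["amp"]]; adp <- pools[["adp"]]; atp <- pools[["atp"]]
  assert_that(all(c(amp, adp, atp) >= 0), "AXP pools must be non-negative")
  total <- amp + adp + atp
  assert_that(total > 0, "AEC undefined for all-zero adenylate pools")
  (atp + 0.5 * adp) / total
}
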