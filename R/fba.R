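# ATP-maximizing flux balance analysis under measured-rate constraints.

# Solve  max/min obj'v  s.t.  S v = 0, extra_A v <= extra_b, lb <= v <= ub.
# Bounds must be finite. Inequality rows get slack variables; the
# resulting equality-constrained box LP goes to the bounded-variable
# revised simplex in simplex.R.
solve_lp <- function(obj, S, lb, ub, maximize = TRUE,
                     extra_A = NULL, extra_b = NULL) {
  n <- length(obj)
  assert_that(all(is.finite(lb)) && all(is.finite(ub)), "LP bounds must be finite")
  assert_that(all(lb <= ub), "LP requires lb <= ub elementwise")
  A <- S
  b <- rep(0, nrow(S))
  cvec <- obj
  lo <- lb
  hi <- ub
  if (!is.null(extra_A)) {
    k <- nrow(extra_A)
    # extra_A v + s = extra_b with slack s in [0, large]
    slack_hi <- pmax(abs(extra_b) + sum(abs(range(lb, ub))) *
                       apply(abs(extra_A), 1, max) * n, 10 * BIG_BOUND)
    A <- rbind(cbind(S, matrix(0, nrow(S), k)),
               cbind(extra_A, diag(k)))
    b <- c(b, extra_b)
    cvec <- c(cvec, rep(0, k))
    lo <- c(lo, rep(0, k))
    hi <- c(hi, slack_hi)
  }
  res <- simplex_bounded(cvec, A, b, lo, hi, maximize = maximize)
  if (res$status == "optimal") {
    v <- res$x[seq_len(n)]
    list(status = "optimal", flux = v, objective = sum(obj * v))
  } else {
    list(status = res$status, flux = rep(NA_real_, n), objective = NA_real_)
  }
}

#' Build a flux problem from measured rates
#'
#' For each measured cell-specific rate `r` with error `e` the bounds of
#' the matching exchange reaction are set to `[r - e, r + e]`; growth and
#' antibody productivity are constrained identically on the biomass and
#' antibody-synthesis pseudo-fluxes. Unmeasured exchanges keep their
#' default bounds. The sign convention is production positive, uptake
#' negative.
#'
#' @param model a `chofba_model`.
#' @param rates a rate table as returned by [rate_table()] /
#'   [estimate_rates()]: data frame with columns `quantity`, `value`,
#'   `error`. Metabolite rates are in fmol/cell/day, `mu` in 1/day,
#'   `mab` in pg/cell/day (converted internally using the model's
#'   antibody molar mass).
#' @return A `chofba_flux_problem`: stoichiometric matrix, bounds,
#'   objective (non-zero only on the ATP drain) and a provenance map
#'   from constrained reaction to the measured rate behind it.
#' @export
constrain_exchanges <- function(model, rates) {
  assert_that(inherits(model, "chofba_model"), "model must be a chofba_model")
  assert_that(is.data.frame(rates) && all(c("quantity", "value", "error") %in% names(rates)),
              "rates must have columns quantity, value, error")
  S <- stoichiometric_matrix(model)
  rxn_ids <- colnames(S)
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  provenance <- list()

  map_reaction <- function(q) {
    if (q == "mu") return(reactions_by_tag(model, "biomass"))
    if (q == "mab") return(reactions_by_tag(model, "mab_synthesis"))
    if (q == "glucose") return("EX_glc")
    if (q == "lactate") return("EX_lac")
    ex <- paste0("EX_", q)
    if (ex %in% rxn_ids) return(ex)
    NA_character_
  }
  for (i in seq_len(nrow(rates))) {
    q <- rates$quantity[i]
    rid <- map_reaction(q)
    assert_that(!is.na(rid) && rid %in% rxn_ids,
                "no exchange/pseudo-flux mapping for measured quantity '%s'", q)
    val <- rates$value[i]
    err <- rates$error[i]
    if (is.na(err)) err <- 0
    assert_that(is.finite(val) && err >= 0,
                "rate for '%s' must be finite with non-negative error", q)
    if (q == "mab") {
      val <- pg_to_fmol(val, model$mab_molar_mass_kda)
      err <- pg_to_fmol(err, model$mab_molar_mass_kda)
    }
    # truncate at the reaction's structural range: a negative net growth
    # rate (decline phase) clamps the irreversible biomass flux to zero
    rxn <- model$reactions[[rid]]
    lb[rid] <- min(max(val - err, rxn$lb), rxn$ub)
    ub[rid] <- max(min(val + err, rxn$ub), rxn$lb)
    provenance[[rid]] <- list(quantity = q, value = val, error = err)
  }
  obj <- setNames(numeric(length(rxn_ids)), rxn_ids)
  obj[reactions_by_tag(model, "atp_drain")] <- 1
  structure(list(S = S, lb = lb, ub = ub, objective = obj,
                 provenance = provenance, model = model),
            class = "chofba_flux_problem")
}

#' @export
print.chofba_flux_problem <- function(x, ...) {
  cat(sprintf("chofba flux problem: %d metabolites x %d reactions, %d measured-rate constraints\n",
              nrow(x$S), ncol(x$S), length(x$provenance)))
  invisible(x)
}

#' Solve the ATP-maximization LP
#'
#' Maximizes the flux through the ATP hydrolysis drain (net cellular ATP
#' production at steady state) subject to `S v = 0` and the problem
#' bounds. If the measured-rate bounds are mutually inconsistent the
#' problem is infeasible; a structured elastic-relaxation diagnosis is
#' then attached to the error, listing the minimal widening of each
#' measured bound that restores feasibility.
#'
#' @param problem a `chofba_flux_problem`.
#' @return A `chofba_flux_solution`: named flux vector (fmol/cell/day),
#'   objective value, solver status.
#' @export
solve_max_atp <- function(problem) {
  res <- solve_lp(problem$objective, problem$S, problem$lb, problem$ub,
                  maximize = TRUE)
  if (res$status == "infeasible") {
    relax <- relax_infeasible(problem)
    msg <- paste0(
      "flux problem infeasible under measured-rate bounds; minimal relaxations (fmol/cell/day): ",
      paste(sprintf("%s: %.4g", names(relax), relax), collapse = ", "))
    stop(structure(class = c("chofba_infeasible", "chofba_error", "error", "condition"),
                   list(message = msg, call = sys.call(-1), relaxation = relax)))
  }
  assert_that(res$status == "optimal", "LP failed with status '%s'", res$status)
  flux <- setNames(res$flux, colnames(problem$S))
  structure(list(flux = flux, objective = res$objective, status = res$status,
                 problem = problem),
            class = "chofba_flux_solution")
}

#' @export
print.chofba_flux_solution <- function(x, ...) {
  cat(sprintf("chofba flux solution (%s): ATP drain = %.4g fmol/cell/day\n",
              x$status, x$objective))
  invisible(x)
}

# Elastic relaxation: minimize total slack added to measured bounds so the
# polytope becomes non-empty; reports per-reaction slack.
relax_infeasible <- function(problem) {
  measured <- names(problem$provenance)
  n <- ncol(problem$S)
  k <- length(measured)
  idx <- match(measured, colnames(problem$S))
  # variables: v (n) then slack s (k), s >= 0
  lb <- c(problem$lb, rep(0, k))
  ub <- c(problem$ub, rep(2 * BIG_BOUND, k))
  # open up the measured bounds — but only within each reaction's
  # structural range (an irreversible pseudo-flux must not run backwards
  # just to absolve an inconsistent measurement) — and couple through
  # slack rows:  v_i - s_i <= ub_i   and   -v_i - s_i <= -lb_i
  for (j in seq_len(k)) {
    rxn <- if (!is.null(problem$model)) problem$model$reactions[[measured[j]]]
    lb[idx[j]] <- if (is.null(rxn)) -BIG_BOUND else rxn$lb
    ub[idx[j]] <- if (is.null(rxn)) BIG_BOUND else rxn$ub
  }
  A <- matrix(0, 2 * k, n + k)
  b <- numeric(2 * k)
  for (j in seq_len(k)) {
    A[2 * j - 1, idx[j]] <- 1;  A[2 * j - 1, n + j] <- -1
    b[2 * j - 1] <- problem$ub[idx[j]]
    A[2 * j, idx[j]] <- -1;     A[2 * j, n + j] <- -1
    b[2 * j] <- -problem$lb[idx[j]]
  }
  Sx <- cbind(problem$S, matrix(0, nrow(problem$S), k))
  obj <- c(numeric(n), rep(1, k))
  res <- solve_lp(obj, Sx, lb, ub, maximize = FALSE, extra_A = A, extra_b = b)
  assert_that(res$status == "optimal", "relaxation diagnosis LP failed")
  slack <- res$flux[n + seq_len(k)]
  setNames(round(slack, 8), measured)
}

#' Flux variability of a reaction
#'
#' Minimum and maximum achievable flux of one reaction subject to the
#' problem constraints. By default the objective is left unconstrained;
#' `optimality_fraction` optionally restricts the polytope to solutions
#' achieving at least that fraction of the ATP optimum.
#'
#' @param problem a `chofba_flux_problem`.
#' @param rxn_id reaction id.
#' @param optimality_fraction `NULL`, or a number in \[0, 1\].
#' @return named numeric `c(min, max)` in fmol/cell/day.
#' @export
flux_variability <- function(problem, rxn_id, optimality_fraction = NULL) {
  assert_that(rxn_id %in% colnames(problem$S), "unknown reaction '%s'", rxn_id)
  extra_A <- NULL; extra_b <- NULL
  if (!is.null(optimality_fraction)) {
    opt <- solve_max_atp(problem)$objective
    extra_A <- matrix(-problem$objective, 1)
    extra_b <- -optimality_fraction * opt
  }
  obj <- setNames(numeric(ncol(problem$S)), colnames(problem$S))
  obj[rxn_id] <- 1
  lo <- solve_lp(obj, problem$S, problem$lb, problem$ub, maximize = FALSE,
                 extra_A = extra_A, extra_b = extra_b)
  hi <- solve_lp(obj, problem$S, problem$lb, problem$ub, maximize = TRUE,
                 extra_A = extra_A, extra_b = extra_b)
  assert_that(lo$status == "optimal" && hi$status == "optimal",
              "flux variability LP failed (%s/%s)", lo$status, hi$status)
  c(min = lo$objective, max = hi$objective)
}

#' Export a flux problem as JSON
#' @param problem a `chofba_flux_problem`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
write_flux_problem <- function(problem, path = NULL) {
  out <- list(
    reactions = colnames(problem$S),
    lb = unname(problem$lb), ub = unname(problem$ub),
    objective = unname(problem$objective),
    provenance = problem$provenance)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
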