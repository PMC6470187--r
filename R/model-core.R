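# Core stoichiometric model types: Metabolite, Reaction, NetworkModel.

REACTION_TAGS <- c("glycolysis", "ppp", "tca", "anaplerosis", "aa_catabolism",
                   "oxphos", "transport", "exchange", "biomass",
                   "mab_synthesis", "atp_drain")

#' Create a metabolite
#'
#' @param id short unique token.
#' @param name human-readable name.
#' @param compartment `"cytosol"` or `"extracellular"`.
#' @param carbon_count non-negative integer, carbon atoms per molecule
#'   (for pseudo-species such as biomass this is the rounded carbon content
#'   per flux unit).
#' @return A `chofba_metabolite` object.
#' @export
metabolite <- function(id, name = id, compartment = c("cytosol", "extracellular"),
                       carbon_count = 0L) {
  compartment <- match.arg(compartment)
  assert_that(is.character(id) && length(id) == 1 && nzchar(id),
              "metabolite id must be a non-empty string")
  assert_that(length(carbon_count) == 1 && is.finite(carbon_count) &&
                carbon_count >= 0 && carbon_count == round(carbon_count),
              "carbon_count of '%s' must be a non-negative integer", id)
  structure(list(id = id, name = name, compartment = compartment,
                 carbon_count = as.integer(carbon_count)),
            class = "chofba_metabolite")
}

#' Create a reaction
#'
#' Stoichiometric coefficients are signed: negative = consumed,
#' positive = produced. Flux units are fmol/cell/day throughout the model
#' layer (the biomass pseudo-flux is in 1/day).
#'
#' @param id short unique token.
#' @param stoichiometry named numeric vector, metabolite id -> coefficient.
#' @param reversible logical flag.
#' @param lb,ub default flux bounds (fmol/cell/day).
#' @param tag functional tag, one of "glycolysis", "ppp", "tca",
#'   "anaplerosis", "aa_catabolism", "oxphos", "transport", "exchange",
#'   "biomass", "mab_synthesis", "atp_drain".
#' @param name human-readable name.
#' @return A `chofba_reaction` object.
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE,
                     lb = if (reversible) -BIG_BOUND else 0, ub = BIG_BOUND,
                     tag = "transport", name = id) {
  assert_that(is.numeric(stoichiometry) && length(stoichiometry) > 0 &&
                !is.null(names(stoichiometry)) && all(nzchar(names(stoichiometry))),
              "reaction '%s': stoichiometry must be a non-empty named numeric vector", id)
  assert_that(tag %in% REACTION_TAGS, "reaction '%s': unknown tag '%s'", id, tag)
  assert_that(lb <= ub, "reaction '%s': lb > ub", id)
  structure(list(id = id, name = name, stoichiometry = stoichiometry,
                 reversible = isTRUE(reversible), lb = lb, ub = ub, tag = tag),
            class = "chofba_reaction")
}

#' Assemble a network model
#'
#' Validates global invariants: unique ids, registered metabolites, carbon
#' balance of all internal reactions, exactly one ATP drain / biomass /
#' antibody-synthesis reaction, and the single-LDH lactate node.
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param po_nadh,po_fadh2 P/O ratios (mol ATP per mol cofactor oxidized).
#' @param biomass_composition named numeric, precursor id -> mmol/g dry weight.
#' @param mab_composition named numeric, amino-acid id -> residues/antibody.
#' @param cell_dry_weight pg dry weight per cell.
#' @param mab_molar_mass_kda antibody molar mass in kDa.
#' @return A `chofba_model` object.
#' @export
network_model <- function(metabolites, reactions, po_nadh = 2.5, po_fadh2 = 1.5,
                          biomass_composition = numeric(), mab_composition = numeric(),
                          cell_dry_weight = 250, mab_molar_mass_kda = DEFAULT_MAB_KDA) {
  met_ids <- vapply(metabolites, `[[`, "", "id")
  assert_that(!anyDuplicated(met_ids), "duplicate metabolite ids")
  rxn_ids <- vapply(reactions, `[[`, "", "id")
  assert_that(!anyDuplicated(rxn_ids), "duplicate reaction ids")
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids

  carbon <- setNames(vapply(metabolites, `[[`, 0L, "carbon_count"), met_ids)
  comp <- setNames(vapply(metabolites, `[[`, "", "compartment"), met_ids)

  for (r in reactions) {
    unknown <- setdiff(names(r$stoichiometry), met_ids)
    assert_that(length(unknown) == 0,
                "reaction '%s' references unknown metabolite(s): %s",
                r$id, paste(unknown, collapse = ", "))
    if (!r$tag %in% c("exchange", "biomass", "mab_synthesis")) {
      resid <- sum(r$stoichiometry * carbon[names(r$stoichiometry)])
      assert_that(abs(resid) < 1e-9,
                  "reaction '%s' is not carbon balanced (residual %g)", r$id, resid)
    }
    if (r$tag == "exchange") {
      touched <- names(r$stoichiometry)
      assert_that(length(touched) == 1 && comp[touched] == "extracellular",
                  "exchange reaction '%s' must touch exactly one extracellular metabolite",
                  r$id)
    }
  }
  tags <- vapply(reactions, `[[`, "", "tag")
  for (t in c("atp_drain", "biomass", "mab_synthesis"))
    assert_that(sum(tags == t) == 1, "model must contain exactly one %s reaction", t)
  assert_that(po_nadh > 0 && po_fadh2 > 0, "P/O ratios must be positive")

  structure(list(metabolites = metabolites, reactions = reactions,
                 po_nadh = po_nadh, po_fadh2 = po_fadh2,
                 biomass_composition = biomass_composition,
                 mab_composition = mab_composition,
                 cell_dry_weight = cell_dry_weight,
                 mab_molar_mass_kda = mab_molar_mass_kda),
            class = "chofba_model")
}

#' @export
print.chofba_model <- function(x, ...) {
  tags <- vapply(x$reactions, `[[`, "", "tag")
  cat("chofba network model\n")
  cat(sprintf("  %d metabolites (%d extracellular), %d reactions\n",
              length(x$metabolites),
              sum(vapply(x$metabolites, `[[`, "", "compartment") == "extracellular"),
              length(x$reactions)))
  cat(sprintf("  P/O ratios: %.2f (NADH), %.2f (FADH2)\n", x$po_nadh, x$po_fadh2))
  cat("  reactions by tag:\n")
  print(table(factor(tags, levels = REACTION_TAGS)))
  invisible(x)
}

#' Carbon residual of a reaction
#'
#' Signed carbon residual `sum(coeff * carbon_count)`; zero for a
#' carbon-balanced reaction. Exchange, biomass and antibody-synthesis
#' pseudo-reactions report a residual too but are exempted from the
#' balanced-model invariant.
#'
#' @param rxn a [reaction()] object.
#' @param carbon_registry named numeric/integer vector, metabolite id ->
#'   carbon atoms (e.g. from [carbon_counts()]).
#' @return signed carbon residual (atoms per unit flux).
#' @export
carbon_balance_check <- function(rxn, carbon_registry) {
  ids <- names(rxn$stoichiometry)
  missing <- setdiff(ids, names(carbon_registry))
  assert_that(length(missing) == 0, "unknown metabolite id(s): %s",
              paste(missing, collapse = ", "))
  sum(rxn$stoichiometry * carbon_registry[ids])
}

#' Carbon counts of all metabolites in a model
#' @param model a `chofba_model`.
#' @return named integer vector, metabolite id -> carbon atoms.
#' @export
carbon_counts <- function(model) {
  setNames(vapply(model$metabolites, `[[`, 0L, "carbon_count"),
           names(model$metabolites))
}

#' Stoichiometric matrix
#'
#' @param model a `chofba_model`.
#' @return numeric matrix (metabolites x reactions) with dimnames; the
#'   column order is the model's reaction order, the row order the model's
#'   metabolite order (both stable).
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

#' Add missing exchange reactions
#'
#' Ensures every extracellular metabolite has exactly one exchange
#' pseudo-reaction (stoichiometry `{met: -1}`, reversible). A positive
#' exchange flux is secretion, a negative one uptake. Idempotent.
#'
#' @param model a `chofba_model`.
#' @return the model, with exchanges added where missing.
#' @export
add_exchange_reactions <- function(model) {
  tags <- vapply(model$reactions, `[[`, "", "tag")
  exchanged <- unlist(lapply(model$reactions[tags == "exchange"],
                             function(r) names(r$stoichiometry)))
  extra <- names(model$metabolites)[
    vapply(model$metabolites, `[[`, "", "compartment") == "extracellular"]
  for (m in setdiff(extra, exchanged)) {
    ex <- reaction(paste0("EX_", sub("_e$", "", m)), setNames(-1, m),
                   reversible = TRUE, tag = "exchange",
                   name = paste("exchange of", m))
    model$reactions[[ex$id]] <- ex
  }
  model
}

#' Reactions by tag or id
#' @param model a `chofba_model`.
#' @param tag functional tag to select.
#' @return character vector of reaction ids.
#' @export
reactions_by_tag <- function(model, tag) {
  tags <- vapply(model$reactions, `[[`, "", "tag")
  names(model$reactions)[tags == tag]
}

#' Export the reaction registry as JSON
#'
#' @param model a `chofba_model`.
#' @param path file to write; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
write_reaction_registry <- function(model, path = NULL) {
  reg <- lapply(model$reactions, function(r)
    list(id = r$id, name = r$name, stoichiometry = as.list(r$stoichiometry),
         reversible = r$reversible, lb = r$lb, ub = r$ub, tag = r$tag))
  js <- jsonlite::toJSON(unname(reg), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
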