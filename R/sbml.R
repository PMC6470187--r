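# SBML Level 3 import/export of the network model.
#
# The document uses SBML L3V1 core: compartments, species (with a
# carbon-count annotation), reactions with stoichiometric
# speciesReferences, and model-level annotations carrying the P/O
# ratios, reaction tags, bounds, and the biomass/antibody composition
# tables. Everything written is read back bit-identically in semantic
# content.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
CHOFBA_NS <- "https://chofba.r-pkg/annotations"

#' Write a model as SBML Level 3
#'
#' @param model a `chofba_model`.
#' @param path file to write.
#' @return invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS,
                            "xmlns:chofba" = CHOFBA_NS,
                            level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "chofba_core")

  ann <- xml2::xml_add_child(mdl, "annotation")
  meta <- xml2::xml_add_child(ann, "chofba:parameters",
                              "xmlns:chofba" = CHOFBA_NS,
                              "chofba:po_nadh" = format(model$po_nadh, digits = 17),
                              "chofba:po_fadh2" = format(model$po_fadh2, digits = 17),
                              "chofba:cell_dry_weight" = format(model$cell_dry_weight, digits = 17),
                              "chofba:mab_molar_mass_kda" = format(model$mab_molar_mass_kda, digits = 17))
  comp_node <- xml2::xml_add_child(meta, "chofba:biomass_composition")
  for (p in names(model$biomass_composition))
    xml2::xml_add_child(comp_node, "chofba:precursor", "chofba:id" = p,
                        "chofba:mmol_per_gdw" = format(model$biomass_composition[[p]], digits = 17))
  mab_node <- xml2::xml_add_child(meta, "chofba:mab_composition")
  for (p in names(model$mab_composition))
    xml2::xml_add_child(mab_node, "chofba:residue", "chofba:id" = p,
                        "chofba:count" = format(model$mab_composition[[p]], digits = 17))

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in c("cytosol", "extracellular"))
    xml2::xml_add_child(comps, "compartment", id = cid, constant = "true")

  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (m in model$metabolites)
    xml2::xml_add_child(sps, "species", id = m$id, name = m$name,
                        compartment = m$compartment,
                        constant = "false", boundaryCondition = "false",
                        hasOnlySubstanceUnits = "false",
                        "chofba:carbon" = as.character(m$carbon_count),
                        "xmlns:chofba" = CHOFBA_NS)

  rxns <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in model$reactions) {
    rn <- xml2::xml_add_child(rxns, "reaction", id = r$id, name = r$name,
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false",
                              "chofba:tag" = r$tag,
                              "chofba:lb" = format(r$lb, digits = 17),
                              "chofba:ub" = format(r$ub, digits = 17),
                              "xmlns:chofba" = CHOFBA_NS)
    lre <- xml2::xml_add_child(rn, "listOfReactants")
    lpr <- xml2::xml_add_child(rn, "listOfProducts")
    for (sid in names(r$stoichiometry)) {
      coef <- r$stoichiometry[[sid]]
      parent <- if (coef < 0) lre else lpr
      xml2::xml_add_child(parent, "speciesReference", species = sid,
                          stoichiometry = format(abs(coef), digits = 17),
                          constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a model from SBML Level 3
#'
#' @param path SBML file written by [write_sbml()] (or compatible L3
#'   core with the package's annotations).
#' @return a validated `chofba_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop_chofba("SBML parse failure: %s", conditionMessage(e)))
  xml2::xml_ns_strip(doc)

  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  assert_that(length(comp_nodes) > 0,
              "SBML document lacks compartment declarations")
  comp_ids <- xml2::xml_attr(comp_nodes, "id")
  assert_that(all(c("cytosol", "extracellular") %in% comp_ids),
              "SBML model must declare cytosol and extracellular compartments")

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  assert_that(length(sp_nodes) > 0, "SBML document has no species")
  mets <- lapply(sp_nodes, function(nd) {
    metabolite(id = xml2::xml_attr(nd, "id"),
               name = xml2::xml_attr(nd, "name"),
               compartment = xml2::xml_attr(nd, "compartment"),
               carbon_count = as.integer(xml2::xml_attr(nd, "carbon") %||% "0"))
  })

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx_nodes, function(nd) {
    st <- numeric()
    for (ref in xml2::xml_find_all(nd, "./listOfReactants/speciesReference"))
      st[xml2::xml_attr(ref, "species")] <-
        -as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    for (ref in xml2::xml_find_all(nd, "./listOfProducts/speciesReference"))
      st[xml2::xml_attr(ref, "species")] <-
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    reaction(id = xml2::xml_attr(nd, "id"),
             name = xml2::xml_attr(nd, "name"),
             stoichiometry = st,
             reversible = identical(xml2::xml_attr(nd, "reversible"), "true"),
             lb = as.numeric(xml2::xml_attr(nd, "lb")),
             ub = as.numeric(xml2::xml_attr(nd, "ub")),
             tag = xml2::xml_attr(nd, "tag"))
  })

  par_node <- xml2::xml_find_first(doc, ".//*[local-name()='parameters']")
  num_attr <- function(a, default) {
    v <- xml2::xml_attr(par_node, a)
    if (is.na(v)) default else as.numeric(v)
  }
  named_table <- function(xpath, id_attr, val_attr) {
    nodes <- xml2::xml_find_all(doc, xpath)
    setNames(as.numeric(xml2::xml_attr(nodes, val_attr)),
             xml2::xml_attr(nodes, id_attr))
  }
  network_model(
    mets, rxns,
    po_nadh = num_attr("po_nadh", 2.5),
    po_fadh2 = num_attr("po_fadh2", 1.5),
    biomass_composition = named_table(
      ".//*[local-name()='biomass_composition']/*[local-name()='precursor']",
      "id", "mmol_per_gdw"),
    mab_composition = named_table(
      ".//*[local-name()='mab_composition']/*[local-name()='residue']",
      "id", "count"),
    cell_dry_weight = num_attr("cell_dry_weight", 250),
    mab_molar_mass_kda = num_attr("mab_molar_mass_kda", DEFAULT_MAB_KDA))
}
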