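# Construction of the reduced CHO central-carbon network.
#
# The network lumps pathways to the resolution at which fed-batch FBA
# results are usually reported: glycolysis at near-reaction resolution,
# one oxidative + one non-oxidative pentose phosphate step, full TCA,
# anaplerosis (pyruvate carboxylase, malic enzyme), one lumped catabolic
# entry per measured amino acid, pooled NADH/FADH2 feeding two oxidative
# phosphorylation reactions, an ATP hydrolysis drain, and pseudo-reactions
# for biomass and antibody synthesis. One intracellular compartment
# (cytosol) is used; mitochondrial shuttles are not resolved, so all
# redox cofactors are pooled before oxidative phosphorylation.

# amino acid metadata: carbon count per molecule
AA_TABLE <- data.frame(
  id = c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly", "his", "ile",
         "leu", "lys", "met", "phe", "pro", "ser", "thr", "trp", "tyr", "val"),
  carbon = c(3L, 6L, 4L, 4L, 3L, 5L, 5L, 2L, 6L, 6L,
             6L, 6L, 5L, 9L, 5L, 3L, 4L, 11L, 9L, 5L),
  stringsAsFactors = FALSE
)

#' Default CHO biomass composition
#'
#' Literature-typical precursor demands for CHO biomass in mmol per gram
#' dry weight: the 20 proteinogenic amino acids (protein), glucose-6-P
#' (carbohydrate), ribulose-5-P (nucleotide ribose), acetyl-CoA (lipid),
#' plus ATP (growth-associated maintenance) and NADPH costs.
#'
#' @param atp_per_gdw growth-associated ATP demand, mmol/g dry weight.
#' @return named numeric vector, precursor id -> mmol/gDW.
#' @export
default_biomass_composition <- function(atp_per_gdw = 35) {
  c(ala = 0.60, arg = 0.28, asn = 0.22, asp = 0.35, cys = 0.06, gln = 0.25,
    glu = 0.38, gly = 0.54, his = 0.14, ile = 0.28, leu = 0.51, lys = 0.44,
    met = 0.12, phe = 0.21, pro = 0.30, ser = 0.33, thr = 0.33, trp = 0.05,
    tyr = 0.16, val = 0.35,
    g6p = 0.18, ru5p = 0.16, accoa = 1.40,
    atp = atp_per_gdw, nadph = 1.30)
}

#' Default IgG1 amino-acid composition
#'
#' Generic residue counts per antibody molecule (two heavy + two light
#' chains, about 1320 residues in total).
#'
#' @return named numeric vector, amino-acid id -> residues per antibody.
#' @export
default_mab_composition <- function() {
  c(ala = 74, arg = 42, asn = 56, asp = 58, cys = 32, gln = 62,
    glu = 72, gly = 90, his = 28, ile = 44, leu = 108, lys = 92,
    met = 18, phe = 52, pro = 94, ser = 150, thr = 112, trp = 26,
    tyr = 58, val = 124)
}

# lumped catabolic entries: list(id, consumed-aa, products, cofactors)
# all carbon balanced against AA_TABLE and central-carbon carbon counts
aa_catabolic_reactions <- function() {
  list(
    # ALT is the only internal carbon source/sink for alanine
    reaction("ALT", c(pyr = -1, glu = -1, ala = 1, akg = 1), reversible = TRUE,
             tag = "aa_catabolism", name = "alanine transaminase"),
    reaction("ARGcat", c(arg = -1, nad = -1, glu = 1, co2 = 1, nadh = 1),
             tag = "aa_catabolism", name = "arginine degradation (lumped)"),
    reaction("ASNcat", c(asn = -1, akg = -1, oaa = 1, glu = 1),
             tag = "aa_catabolism", name = "asparaginase + transamination (lumped)"),
    reaction("ASPTA", c(asp = -1, akg = -1, oaa = 1, glu = 1), reversible = TRUE,
             tag = "aa_catabolism", name = "aspartate transaminase"),
    reaction("CYScat", c(cys = -1, pyr = 1),
             tag = "aa_catabolism", name = "cysteine degradation (lumped)"),
    reaction("GLS", c(gln = -1, glu = 1),
             tag = "aa_catabolism", name = "glutaminase"),
    reaction("GDH", c(glu = -1, nad = -1, akg = 1, nadh = 1), reversible = TRUE,
             tag = "aa_catabolism", name = "glutamate dehydrogenase"),
    reaction("GLYcat", c(gly = -1, nad = -1, co2 = 2, nadh = 1),
             tag = "aa_catabolism", name = "glycine cleavage (lumped)"),
    reaction("HIScat", c(his = -1, glu = 1, co2 = 1),
             tag = "aa_catabolism", name = "histidine degradation (lumped)"),
    reaction("ILEcat", c(ile = -1, nad = -2, fad = -1,
                         accoa = 1, succoa = 1, nadh = 2, fadh2 = 1),
             tag = "aa_catabolism", name = "isoleucine degradation (lumped)"),
    reaction("LEUcat", c(leu = -1, nad = -1, fad = -1, accoa = 3, nadh = 1, fadh2 = 1),
             tag = "aa_catabolism", name = "leucine degradation (lumped)"),
    reaction("LYScat", c(lys = -1, nad = -4, accoa = 2, co2 = 2, nadh = 4),
             tag = "aa_catabolism", name = "lysine degradation (lumped)"),
    reaction("METcat", c(met = -1, nad = -1, succoa = 1, co2 = 1, nadh = 1),
             tag = "aa_catabolism", name = "methionine degradation (lumped)"),
    reaction("PHEcat", c(phe = -1, nad = -1, fum = 1, accoa = 2, co2 = 1, nadh = 1),
             tag = "aa_catabolism", name = "phenylalanine degradation (lumped)"),
    reaction("PROcat", c(pro = -1, fad = -1, nad = -1, glu = 1, fadh2 = 1, nadh = 1),
             tag = "aa_catabolism", name = "proline degradation (lumped)"),
    reaction("SERcat", c(ser = -1, pyr = 1),
             tag = "aa_catabolism", name = "serine dehydratase"),
    reaction("THRcat", c(thr = -1, nad = -1, succoa = 1, nadh = 1),
             tag = "aa_catabolism", name = "threonine degradation (lumped)"),
    reaction("TRPcat", c(trp = -1, nad = -3, pyr = 1, accoa = 2, co2 = 4, nadh = 3),
             tag = "aa_catabolism", name = "tryptophan degradation (lumped)"),
    reaction("TYRcat", c(tyr = -1, nad = -1, fum = 1, accoa = 2, co2 = 1, nadh = 1),
             tag = "aa_catabolism", name = "tyrosine degradation (lumped)"),
    reaction("VALcat", c(val = -1, nad = -2, fad = -1,
                         succoa = 1, co2 = 1, nadh = 2, fadh2 = 1),
             tag = "aa_catabolism", name = "valine degradation (lumped)")
  )
}

#' Build the reduced CHO core network
#'
#' Constructs the central-carbon model: glycolysis, lumped pentose
#' phosphate pathway, lactate dehydrogenase, full TCA cycle with
#' GTP-yielding succinyl-CoA synthetase and FADH2-yielding succinate
#' dehydrogenase, anaplerosis (pyruvate carboxylase, malic enzyme),
#' glutaminolysis, one lumped catabolic entry per proteinogenic amino
#' acid, two oxidative phosphorylation reactions parameterized by P/O
#' ratios, an ATP hydrolysis drain, biomass and antibody synthesis
#' pseudo-reactions, membrane transports and boundary exchanges.
#'
#' @param po_nadh,po_fadh2 P/O ratios: mol ATP per mol NADH (default 2.5)
#'   or FADH2 (default 1.5) oxidized.
#' @param biomass_composition precursor demands, mmol/gDW
#'   (default [default_biomass_composition()]).
#' @param mab_composition residues per antibody
#'   (default [default_mab_composition()]).
#' @param cell_dry_weight pg dry weight per cell (default 250), used to
#'   scale the biomass reaction so its flux unit is the growth rate in
#'   1/day.
#' @param mab_molar_mass_kda antibody molar mass in kDa (default 150),
#'   used for pg <-> fmol conversion of the antibody flux.
#' @param atp_per_mab_residue ATP cost per peptide bond in antibody
#'   synthesis (default 4).
#' @return A validated `chofba_model` with all exchanges in place.
#' @examples
#' m <- build_core_model()
#' m$reactions$OXPHOS_NADH$stoichiometry["atp"]  # 2.5
#' @export
build_core_model <- function(po_nadh = 2.5, po_fadh2 = 1.5,
                             biomass_composition = default_biomass_composition(),
                             mab_composition = default_mab_composition(),
                             cell_dry_weight = 250,
                             mab_molar_mass_kda = DEFAULT_MAB_KDA,
                             atp_per_mab_residue = 4) {
  assert_that(po_nadh > 0 && po_fadh2 > 0, "P/O ratios must be positive")
  assert_that(length(biomass_composition) > 0 && all(biomass_composition >= 0),
              "biomass composition must be non-empty and non-negative")

  mets <- list()
  add_met <- function(id, carbon, compartment = "cytosol", name = id) {
    mets[[id]] <<- metabolite(id, name, compartment, carbon)
  }
  # central carbon (cytosol)
  add_met("glc", 6); add_met("g6p", 6); add_met("f6p", 6); add_met("fbp", 6)
  add_met("gap", 3); add_met("pg3", 3); add_met("pep", 3); add_met("pyr", 3)
  add_met("lac", 3); add_met("ru5p", 5)
  add_met("accoa", 2, name = "acetyl-CoA (acetyl carbon)")
  add_met("cit", 6); add_met("akg", 5); add_met("succoa", 4)
  add_met("succ", 4); add_met("fum", 4); add_met("mal", 4); add_met("oaa", 4)
  add_met("co2", 1); add_met("o2", 0)
  # cofactors (carbon-free bookkeeping species)
  for (cf in c("atp", "adp", "nad", "nadh", "fad", "fadh2", "nadp", "nadph"))
    add_met(cf, 0)
  # amino acids, cytosolic
  for (i in seq_len(nrow(AA_TABLE))) add_met(AA_TABLE$id[i], AA_TABLE$carbon[i])
  # extracellular species
  add_met("glc_e", 6, "extracellular"); add_met("lac_e", 3, "extracellular")
  add_met("co2_e", 1, "extracellular"); add_met("o2_e", 0, "extracellular")
  for (i in seq_len(nrow(AA_TABLE)))
    add_met(paste0(AA_TABLE$id[i], "_e"), AA_TABLE$carbon[i], "extracellular")

  # biomass pseudo-species: carbon content per unit flux (1/day) is
  # dry weight * sum(comp_i * C_i); rounded to an integer atom count
  carbon_reg <- setNames(vapply(mets, `[[`, 0L, "carbon_count"), names(mets))
  bio_carbon <- sum(vapply(names(biomass_composition), function(p) {
    if (p %in% names(carbon_reg)) biomass_composition[[p]] * carbon_reg[[p]] else 0
  }, 0)) * cell_dry_weight
  add_met("biomass_e", round(bio_carbon), "extracellular", name = "biomass")
  mab_carbon <- sum(mab_composition * AA_TABLE$carbon[match(names(mab_composition), AA_TABLE$id)])
  add_met("mab_e", round(mab_carbon), "extracellular", name = "antibody")

  rxns <- list(
    # glycolysis
    reaction("GLUT", c(glc_e = -1, glc = 1), tag = "transport", name = "glucose transport"),
    reaction("HK", c(glc = -1, atp = -1, g6p = 1, adp = 1),
             tag = "glycolysis", name = "hexokinase"),
    reaction("PGI", c(g6p = -1, f6p = 1), reversible = TRUE,
             tag = "glycolysis", name = "phosphoglucose isomerase"),
    reaction("PFK", c(f6p = -1, atp = -1, fbp = 1, adp = 1),
             tag = "glycolysis", name = "phosphofructokinase"),
    reaction("ALD_TPI", c(fbp = -1, gap = 2),
             tag = "glycolysis", name = "aldolase + triose phosphate isomerase (lumped)"),
    reaction("GAPD_PGK", c(gap = -1, nad = -1, adp = -1, pg3 = 1, nadh = 1, atp = 1),
             tag = "glycolysis", name = "GAPDH + phosphoglycerate kinase (lumped)"),
    reaction("PGM_ENO", c(pg3 = -1, pep = 1), reversible = TRUE,
             tag = "glycolysis", name = "phosphoglycerate mutase + enolase (lumped)"),
    reaction("PK", c(pep = -1, adp = -1, pyr = 1, atp = 1),
             tag = "glycolysis", name = "pyruvate kinase"),
    # lactate: single internal reaction (reversible for consumption phenotypes)
    reaction("LDH", c(pyr = -1, nadh = -1, lac = 1, nad = 1), reversible = TRUE,
             tag = "glycolysis", name = "lactate dehydrogenase"),
    # pentose phosphate pathway, lumped
    reaction("PPP_OX", c(g6p = -1, nadp = -2, ru5p = 1, co2 = 1, nadph = 2),
             tag = "ppp", name = "oxidative PPP (lumped)"),
    reaction("PPP_NONOX", c(ru5p = -3, f6p = 2, gap = 1), reversible = TRUE,
             tag = "ppp", name = "non-oxidative PPP (lumped)"),
    # TCA
    reaction("PDH", c(pyr = -1, nad = -1, accoa = 1, co2 = 1, nadh = 1),
             tag = "tca", name = "pyruvate dehydrogenase"),
    reaction("CS", c(accoa = -1, oaa = -1, cit = 1),
             tag = "tca", name = "citrate synthase"),
    reaction("IDH", c(cit = -1, nad = -1, akg = 1, co2 = 1, nadh = 1),
             tag = "tca", name = "aconitase + isocitrate dehydrogenase (lumped)"),
    reaction("AKGDH", c(akg = -1, nad = -1, succoa = 1, co2 = 1, nadh = 1),
             tag = "tca", name = "alpha-ketoglutarate dehydrogenase"),
    reaction("SCS", c(succoa = -1, adp = -1, succ = 1, atp = 1),
             tag = "tca", name = "succinyl-CoA synthetase (GTP-yielding)"),
    reaction("SDH", c(succ = -1, fad = -1, fum = 1, fadh2 = 1),
             tag = "tca", name = "succinate dehydrogenase"),
    reaction("FUM", c(fum = -1, mal = 1), reversible = TRUE,
             tag = "tca", name = "fumarase"),
    reaction("MDH", c(mal = -1, nad = -1, oaa = 1, nadh = 1), reversible = TRUE,
             tag = "tca", name = "malate dehydrogenase"),
    # anaplerosis
    reaction("PC", c(pyr = -1, co2 = -1, atp = -1, oaa = 1, adp = 1),
             tag = "anaplerosis", name = "pyruvate carboxylase"),
    reaction("ME", c(mal = -1, nadp = -1, pyr = 1, co2 = 1, nadph = 1),
             tag = "anaplerosis", name = "malic enzyme"),
    # cataplerotic exit from the TCA; without it surplus anaplerotic
    # carbon could only leave via malic enzyme, which the NADPH balance caps
    reaction("PEPCK", c(oaa = -1, atp = -1, pep = 1, co2 = 1, adp = 1),
             tag = "anaplerosis", name = "PEP carboxykinase"),
    # oxidative phosphorylation (pooled cofactors)
    reaction("OXPHOS_NADH",
             c(nadh = -1, o2 = -0.5, adp = -po_nadh, nad = 1, atp = po_nadh),
             tag = "oxphos", name = "oxidative phosphorylation of NADH"),
    reaction("OXPHOS_FADH2",
             c(fadh2 = -1, o2 = -0.5, adp = -po_fadh2, fad = 1, atp = po_fadh2),
             tag = "oxphos", name = "oxidative phosphorylation of FADH2"),
    # ATP drain (objective of the FBA)
    reaction("ATP_DRAIN", c(atp = -1, adp = 1),
             tag = "atp_drain", name = "ATP hydrolysis drain"),
    # gas transports
    reaction("CO2t", c(co2 = -1, co2_e = 1), reversible = TRUE,
             tag = "transport", name = "CO2 transport"),
    reaction("O2t", c(o2_e = -1, o2 = 1),
             tag = "transport", name = "O2 transport"),
    # lactate transport
    reaction("LACt", c(lac = -1, lac_e = 1), reversible = TRUE,
             tag = "transport", name = "lactate transport")
  )
  # amino-acid transports and catabolism
  for (aa in AA_TABLE$id) {
    rxns[[length(rxns) + 1]] <-
      reaction(paste0(toupper(aa), "t"),
               setNames(c(-1, 1), c(paste0(aa, "_e"), aa)), reversible = TRUE,
               tag = "transport", name = paste(aa, "transport"))
  }
  rxns <- c(rxns, aa_catabolic_reactions())

  # biomass pseudo-reaction: flux unit 1/day; coefficient of each
  # precursor is -comp[mmol/gDW] * DW[pg/cell] = -fmol/(cell * unit flux)
  bio_st <- -biomass_composition * cell_dry_weight
  names(bio_st) <- names(biomass_composition)
  # ATP hydrolysis: release ADP; NADPH oxidation: release NADP
  if ("atp" %in% names(bio_st)) bio_st["adp"] <- -bio_st[["atp"]]
  if ("nadph" %in% names(bio_st)) bio_st["nadp"] <- -bio_st[["nadph"]]
  bio_st["biomass_e"] <- 1
  rxns[[length(rxns) + 1]] <- reaction("BIOMASS", bio_st, lb = 0, ub = 5,
                                       tag = "biomass", name = "biomass synthesis")

  # antibody synthesis: flux unit fmol antibody/cell/day
  mab_st <- -mab_composition
  names(mab_st) <- names(mab_composition)
  n_res <- sum(mab_composition)
  mab_st["atp"] <- -atp_per_mab_residue * n_res
  mab_st["adp"] <- atp_per_mab_residue * n_res
  mab_st["mab_e"] <- 1
  rxns[[length(rxns) + 1]] <- reaction("MAB", mab_st, lb = 0, ub = 10,
                                       tag = "mab_synthesis", name = "antibody synthesis")

  model <- network_model(mets, rxns, po_nadh = po_nadh, po_fadh2 = po_fadh2,
                         biomass_composition = biomass_composition,
                         mab_composition = mab_composition,
                         cell_dry_weight = cell_dry_weight,
                         mab_molar_mass_kda = mab_molar_mass_kda)
  add_exchange_reactions(model)
}
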