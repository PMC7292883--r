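## Deterministic generators for every input the pipeline consumes: a toy
## aerobic diazotroph network (nitrogenase + ammonium assimilation, lumped
## glycolysis/Entner-Doudoroff/TCA/oxidative phosphorylation, a six-step
## alginate branch and a PHB branch), Biolog-style plates with ground-truth
## calls, proteomes of known composition, and homology tables spanning the
## curation thresholds. All generators are pure functions of their
## arguments and seed.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.toy_metabolites <- function() {
  m <- function(id, formula, charge, name = id) {
    comp <- sub("^.*_", "", id)
    data.frame(id = id, name = name, formula = formula, charge = charge,
               compartment = comp, stringsAsFactors = FALSE)
  }
  rbind(
    ## extracellular nutrients and products
    m("glc__D_e", "C6H12O6", 0, "D-glucose"),
    m("fru_e", "C6H12O6", 0, "D-fructose"),
    m("gal_e", "C6H12O6", 0, "D-galactose"),
    m("man_e", "C6H12O6", 0, "D-mannose"),
    m("sucr_e", "C12H22O11", 0, "sucrose"),
    m("mnl_e", "C6H14O6", 0, "D-mannitol"),
    m("glyc_e", "C3H8O3", 0, "glycerol"),
    m("pyr_e", "C3H3O3", -1, "pyruvate"),
    m("glu__L_e", "C5H8NO4", -1, "L-glutamate"),
    m("nh4_e", "H4N", 1, "ammonium"),
    m("n2_e", "N2", 0, "dinitrogen"),
    m("o2_e", "O2", 0, "oxygen"),
    m("co2_e", "CO2", 0, "carbon dioxide"),
    m("h2_e", "H2", 0, "hydrogen"),
    m("h_e", "H", 1, "proton"),
    m("h2o_e", "H2O", 0, "water"),
    m("pi_e", "HO4P", -2, "phosphate"),
    m("alg_e", "C6H10O7", 0, "alginate (mannuronate unit)"),
    ## declared-but-disconnected decoy sources (no transporter exists)
    m("lcts_e", "C12H22O11", 0, "lactose"),
    m("acon_e", "C6H3O6", -3, "cis-aconitate"),
    m("xyl__D_e", "C5H10O5", 0, "D-xylose"),
    m("arab__L_e", "C5H10O5", 0, "L-arabinose"),
    m("malt_e", "C12H22O11", 0, "maltose"),
    m("tre_e", "C12H22O11", 0, "trehalose"),
    ## periplasm
    m("glc__D_p", "C6H12O6", 0, "D-glucose"),
    m("alg_p", "C6H10O7", 0, "alginate (mannuronate unit)"),
    ## cytoplasm
    m("glc__D_c", "C6H12O6", 0, "D-glucose"),
    m("fru_c", "C6H12O6", 0, "D-fructose"),
    m("gal_c", "C6H12O6", 0, "D-galactose"),
    m("man_c", "C6H12O6", 0, "D-mannose"),
    m("sucr_c", "C12H22O11", 0, "sucrose"),
    m("mnl_c", "C6H14O6", 0, "D-mannitol"),
    m("glyc_c", "C3H8O3", 0, "glycerol"),
    m("pyr_c", "C3H3O3", -1, "pyruvate"),
    m("glu__L_c", "C5H8NO4", -1, "L-glutamate"),
    m("akg_c", "C5H4O5", -2, "2-oxoglutarate"),
    m("f6p_c", "C6H11O9P", -2, "fructose 6-phosphate"),
    m("man6p_c", "C6H11O9P", -2, "mannose 6-phosphate"),
    m("man1p_c", "C6H11O9P", -2, "mannose 1-phosphate"),
    m("adpman_c", "C16H23N5O15P2", -2, "ADP-mannose"),
    m("adpmanur_c", "C16H20N5O16P2", -3, "ADP-mannuronate"),
    m("alg_c", "C6H10O7", 0, "alginate (mannuronate unit)"),
    m("ppi_c", "HO7P2", -3, "diphosphate"),
    m("atp_c", "C10H12N5O13P3", -4, "ATP"),
    m("adp_c", "C10H12N5O10P2", -3, "ADP"),
    m("pi_c", "HO4P", -2, "phosphate"),
    m("h_c", "H", 1, "proton"),
    m("h2o_c", "H2O", 0, "water"),
    m("o2_c", "O2", 0, "oxygen"),
    m("co2_c", "CO2", 0, "carbon dioxide"),
    m("h2_c", "H2", 0, "hydrogen"),
    m("nh4_c", "H4N", 1, "ammonium"),
    m("n2_c", "N2", 0, "dinitrogen"),
    m("nad_c", "C21H26N7O14P2", -1, "NAD+"),
    m("nadh_c", "C21H27N7O14P2", -2, "NADH"),
    m("nadp_c", "C21H25N7O17P3", -3, "NADP+"),
    m("nadph_c", "C21H26N7O17P3", -4, "NADPH"),
    m("fdxo_c", "X", 0, "ferredoxin (oxidised)"),
    m("fdxr_c", "XH", 0, "ferredoxin (reduced)"),
    m("coa_c", "C21H32N7O16P3S", -4, "coenzyme A"),
    m("accoa_c", "C23H34N7O17P3S", -4, "acetyl-CoA"),
    m("aacoa_c", "C25H36N7O18P3S", -4, "acetoacetyl-CoA"),
    m("phb_c", "C4H6O2", 0, "PHB (3-hydroxybutyrate unit)"))
}

.toy_reactions <- function() {
  rx <- function(id, stoich, lb, ub, subsystem, gpr = NULL, name = id,
                 pseudo = FALSE)
    reaction(id, stoich, lb = lb, ub = ub, name = name, subsystem = subsystem,
             gpr = parse_gpr(gpr), pseudo = pseudo)
  ex <- function(met, lb = 0)
    rx(paste0("EX_", met), stats::setNames(-1, met), lb, 1000, "Exchange",
       name = paste("exchange of", met))
  tr <- function(id, from, to, lb, ub, gpr = NULL)
    rx(id, stats::setNames(c(-1, 1), c(from, to)), lb, ub,
       "Transport", gpr = gpr)
  list(
    ## -- exchanges: default medium is glucose + ammonium, minerals open
    ex("glc__D_e", -10), ex("fru_e"), ex("gal_e"), ex("man_e"), ex("sucr_e"),
    ex("mnl_e"), ex("glyc_e"), ex("pyr_e"), ex("glu__L_e"),
    ex("nh4_e", -1000), ex("n2_e"),
    ex("o2_e", -1000), ex("co2_e", -1000), ex("h2_e", -1000),
    ex("h_e", -1000), ex("h2o_e", -1000), ex("pi_e", -1000),
    ex("alg_e"),
    ex("lcts_e"), ex("acon_e"), ex("xyl__D_e"), ex("arab__L_e"),
    ex("malt_e"), ex("tre_e"),
    ## -- transport
    tr("GLCtex", "glc__D_e", "glc__D_p", 0, 1000, "ptsG or galP"),
    tr("GLCtpp", "glc__D_p", "glc__D_c", 0, 1000, "ptsG"),
    tr("FRUt", "fru_e", "fru_c", 0, 1000, "fruA"),
    tr("GALt", "gal_e", "gal_c", 0, 1000, "galP"),
    tr("MANt", "man_e", "man_c", 0, 1000, "manX"),
    tr("SUCRt", "sucr_e", "sucr_c", 0, 1000, "cscB"),
    tr("MNLt", "mnl_e", "mnl_c", 0, 1000, "mtlA"),
    tr("GLYCt", "glyc_e", "glyc_c", 0, 1000, "glpF"),
    tr("PYRt", "pyr_e", "pyr_c", 0, 1000, "pyrP"),
    tr("GLUt", "glu__L_e", "glu__L_c", 0, 1000, "gltP"),
    tr("NH4t", "nh4_e", "nh4_c", -1000, 1000, "amtB"),
    tr("N2t", "n2_e", "n2_c", 0, 1000),
    tr("O2t", "o2_e", "o2_c", -1000, 1000),
    tr("CO2t", "co2_c", "co2_e", -1000, 1000),
    tr("H2t", "h2_c", "h2_e", -1000, 1000),
    tr("Ht", "h_c", "h_e", -1000, 1000),
    tr("H2Ot", "h2o_c", "h2o_e", -1000, 1000),
    tr("PIt", "pi_e", "pi_c", 0, 1000, "pitA"),
    tr("ALGtex", "alg_p", "alg_e", 0, 1000, "algJ"),
    ## -- carbohydrate catabolism (lumped, element/charge balanced)
    rx("HEX", c(glc__D_c = -1, atp_c = -1, f6p_c = 1, adp_c = 1, h_c = 1),
       0, 1000, "Carbohydrate metabolism", "glk and pgi"),
    rx("GLYCLUMP", c(glc__D_c = -1, nad_c = -2, adp_c = -2, pi_c = -2,
                     pyr_c = 2, nadh_c = 2, h_c = 2, atp_c = 2, h2o_c = 2),
       0, 1000, "Carbohydrate metabolism", "pgi and pfkA and eno and pyk",
       name = "glycolysis (lumped)"),
    rx("EDLUMP", c(glc__D_c = -1, nad_c = -1, nadp_c = -1, adp_c = -1,
                   pi_c = -1, pyr_c = 2, nadh_c = 1, nadph_c = 1, atp_c = 1,
                   h2o_c = 1, h_c = 3),
       0, 1000, "Carbohydrate metabolism", "edd and eda",
       name = "Entner-Doudoroff pathway (lumped)"),
    rx("FRUI", c(fru_c = -1, glc__D_c = 1), -1000, 1000,
       "Carbohydrate metabolism", "xylA"),
    rx("GALI", c(gal_c = -1, glc__D_c = 1), 0, 1000,
       "Carbohydrate metabolism", "galM"),
    rx("MANI", c(man_c = -1, glc__D_c = 1), 0, 1000,
       "Carbohydrate metabolism", "manA"),
    rx("SUCRH", c(sucr_c = -1, h2o_c = -1, glc__D_c = 1, fru_c = 1),
       0, 1000, "Carbohydrate metabolism", "sacA"),
    rx("MNLDH", c(mnl_c = -1, nad_c = -1, fru_c = 1, nadh_c = 1, h_c = 1),
       0, 1000, "Carbohydrate metabolism", "mtlD"),
    rx("GLYCDEG", c(glyc_c = -1, nad_c = -2, adp_c = -1, pi_c = -1,
                    pyr_c = 1, nadh_c = 2, atp_c = 1, h2o_c = 1, h_c = 2),
       0, 1000, "Carbohydrate metabolism", "glpK and glpD"),
    ## -- TCA cycle (lumped) and acetyl-CoA node
    rx("PDH", c(pyr_c = -1, coa_c = -1, nad_c = -1,
                accoa_c = 1, co2_c = 1, nadh_c = 1),
       0, 1000, "TCA cycle", "aceE and aceF and lpdA"),
    rx("TCALUMP", c(pyr_c = -1, nad_c = -5, h2o_c = -3,
                    co2_c = 3, nadh_c = 5, h_c = 4),
       0, 1000, "TCA cycle", "gltA and sdhA and mdh",
       name = "pyruvate oxidation via TCA (lumped)"),
    rx("AKGSYN", c(pyr_c = -2, nad_c = -2, h2o_c = -1,
                   akg_c = 1, co2_c = 1, nadh_c = 2, h_c = 2),
       0, 1000, "TCA cycle", "gltA and acnB and icd"),
    rx("AKGOX", c(akg_c = -1, nad_c = -8, h2o_c = -5,
                  co2_c = 5, nadh_c = 8, h_c = 6),
       0, 1000, "TCA cycle", "sucA and sucB and lpdA",
       name = "2-oxoglutarate oxidation (lumped)"),
    rx("ACOX", c(accoa_c = -1, h2o_c = -3, nad_c = -4,
                 co2_c = 2, coa_c = 1, nadh_c = 4, h_c = 4),
       0, 1000, "TCA cycle", "gltA and mdh"),
    ## -- energy metabolism / oxidative phosphorylation
    rx("OXPHOS", c(nadh_c = -1, o2_c = -0.5, h_c = -3, adp_c = -2, pi_c = -2,
                   nad_c = 1, atp_c = 2, h2o_c = 3),
       0, 1000, "Oxidative phosphorylation", "nuoA and cyoB and atpA",
       name = "respiratory chain + ATP synthase (lumped, P/O = 2)"),
    rx("THD", c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
       0, 1000, "Oxidative phosphorylation", "pntA"),
    rx("FNOR", c(nadh_c = -1, h_c = -1, fdxo_c = -2, nad_c = 1, fdxr_c = 2),
       0, 1000, "Oxidative phosphorylation", "fpr"),
    rx("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
       0, 1000, "Energy metabolism", name = "ATP maintenance"),
    rx("PPA", c(ppi_c = -1, h2o_c = -1, pi_c = 2, h_c = 1),
       0, 1000, "Energy metabolism", "ppa"),
    ## -- nitrogen fixation and ammonium assimilation
    rx("NIT", c(n2_c = -1, fdxr_c = -8, atp_c = -16, h2o_c = -16,
                nh4_c = 2, h2_c = 1, fdxo_c = 8, adp_c = 16, pi_c = 16,
                h_c = 14),
       0, 1000, "Nitrogen metabolism", "nifH and nifD and nifK",
       name = "Mo-nitrogenase (16 ATP per N2)"),
    rx("GLUDy", c(akg_c = -1, nh4_c = -1, h_c = -1, nadph_c = -1,
                  glu__L_c = 1, h2o_c = 1, nadp_c = 1),
       -1000, 1000, "Amino acid metabolism", "gdhA",
       name = "glutamate dehydrogenase (NADPH)"),
    ## -- PHB branch (storage polymer from acetoacetyl-CoA)
    rx("PHAA", c(accoa_c = -2, aacoa_c = 1, coa_c = 1),
       0, 1000, "Secondary metabolites biosynthesis", "phbA",
       name = "acetyl-CoA acetyltransferase"),
    rx("PHBS", c(aacoa_c = -1, nadph_c = -1, h_c = -1,
                 phb_c = 1, coa_c = 1, nadp_c = 1),
       0, 1000, "Secondary metabolites biosynthesis", "phbB and phbC",
       name = "PHB synthesis (reductase + synthase, per monomer)"),
    ## -- alginate branch: six reactions to the periplasmic polymer unit
    rx("PMI", c(f6p_c = -1, man6p_c = 1), -1000, 1000,
       "Glycan biosynthesis", "algA"),
    rx("PMM", c(man6p_c = -1, man1p_c = 1), -1000, 1000,
       "Glycan biosynthesis", "algC"),
    rx("MAN1PT", c(man1p_c = -1, atp_c = -1, h_c = -1,
                   adpman_c = 1, ppi_c = 1),
       0, 1000, "Glycan biosynthesis", "algA"),
    rx("ADPMANDH", c(adpman_c = -1, nad_c = -2, h2o_c = -1,
                     adpmanur_c = 1, nadh_c = 2, h_c = 3),
       0, 1000, "Glycan biosynthesis", "algD"),
    rx("ALGPOLY", c(adpmanur_c = -1, h2o_c = -1, alg_c = 1, adp_c = 1),
       0, 1000, "Glycan biosynthesis", "alg8 and alg44"),
    rx("ALGT", c(alg_c = -1, alg_p = 1), 0, 1000,
       "Glycan biosynthesis", "algG and algE",
       name = "alginate epimerisation/export to periplasm"),
    ## -- biomass (pseudo-reaction; flux = growth rate in 1/h)
    rx("BOF", c(glu__L_c = -40, atp_c = -320, h2o_c = -320, nadph_c = -80,
                adp_c = 320, pi_c = 320, h_c = 320, nadp_c = 80),
       0, 1000, "Biomass and maintenance functions", name = "biomass",
       pseudo = TRUE))
}

.toy_defect_reactions <- list(
  unbalanced = function() reaction(
    "QCDEF_H2OSPLIT", c(h2o_c = -1, h2_c = 1), lb = 0, ub = 1000,
    name = "defect: water splitting with oxygen lost",
    subsystem = "Carbohydrate metabolism"),
  atp_cycle = function() reaction(
    "QCDEF_ATPFREE", c(adp_c = -1, pi_c = -1, h_c = -1, atp_c = 1, h2o_c = 1),
    lb = 0, ub = 1000,
    name = "defect: uncosted ATP regeneration",
    subsystem = "Energy metabolism"),
  orphan_met = function() reaction(
    "QCDEF_ORPHSYN", c(glc__D_c = -1, orphan__X_c = 1), lb = 0, ub = 1000,
    name = "defect: synthesis of a never-consumed metabolite",
    subsystem = "Carbohydrate metabolism"))

#' Generate the toy diazotroph model
#'
#' A deterministic three-compartment network (~70 reactions) with: uptake
#' of eight usable carbon sources (glucose, fructose, galactose, mannose,
#' sucrose, mannitol, glycerol, pyruvate) plus glutamate; six
#' declared-but-disconnected decoy sources (negative plate ground truth);
#' lumped glycolysis and Entner-Doudoroff routes; lumped TCA and
#' oxidative phosphorylation (P/O = 2) with oxygen exchange; the canonical
#' Mo-nitrogenase N2 + 8 H+ + 8 e- + 16 ATP -> 2 NH3 + H2 (electrons via a
#' ferredoxin couple); ammonium uptake with glutamate-dehydrogenase
#' assimilation; a six-reaction alginate branch ending in the periplasm; a
#' PHB branch from acetoacetyl-CoA; and a lumped amino-acid biomass
#' objective. Every internal reaction is element- and charge-balanced.
#' Optional defects inject specific QC failures.
#'
#' @param seed integer; the network is structurally deterministic, the seed
#'   only fixes any future stochastic decoration (kept for interface
#'   uniformity with the other generators).
#' @param defects character subset of \code{"unbalanced"} (an
#'   oxygen-losing water-splitting reaction, caught only by the mass
#'   balance audit), \code{"atp_cycle"} (a balanced uncosted ATP
#'   regeneration, caught only by the ATP energy-cycle check) and
#'   \code{"orphan_met"} (a produced-but-never-consumed metabolite, caught
#'   only by dead-end classification).
#' @return list with \code{model} (a validated \code{metabolic_model}) and
#'   \code{manifest} (declared counts, connectable sources, media,
#'   ground-truth growth calls and injected defects).
#' @export
make_toy_diazotroph <- function(seed = 1, defects = character()) {
  bad <- setdiff(defects, names(.toy_defect_reactions))
  if (length(bad)) stop("unknown defects: ", paste(bad, collapse = ", "))
  mets <- .toy_metabolites()
  rxns <- .toy_reactions()
  if ("orphan_met" %in% defects)
    mets <- rbind(mets, data.frame(id = "orphan__X_c", name = "orphan metabolite",
                                   formula = "C6H12O6", charge = 0,
                                   compartment = "c", stringsAsFactors = FALSE))
  for (d in defects) rxns <- c(rxns, list(.toy_defect_reactions[[d]]()))
  model <- metabolic_model(id = "toy_diazotroph",
                           metabolites = mets, reactions = rxns,
                           objective = "BOF")
  carbon_sources <- c("glc__D_e", "fru_e", "gal_e", "man_e", "sucr_e",
                      "mnl_e", "glyc_e", "pyr_e", "glu__L_e")
  decoys <- c("lcts_e", "acon_e", "xyl__D_e", "arab__L_e", "malt_e", "tre_e")
  detector <- c(unbalanced = "element_balance", atp_cycle = "energy_cycle_atp",
                orphan_met = "dead_end")
  manifest <- list(
    seed = seed,
    n_reactions = length(model$reactions),
    n_metabolites = nrow(model$metabolites),
    n_genes = length(model$genes),
    compartments = names(model$compartments),
    objective = "BOF",
    carbon_sources = carbon_sources,
    nitrogen_sources = c("nh4_e", "glu__L_e"),
    decoy_sources = decoys,
    defects = if (length(defects))
      data.frame(defect = defects,
                 reaction = vapply(defects, function(d)
                   .toy_defect_reactions[[d]]()$id, ""),
                 detected_by = detector[defects],
                 stringsAsFactors = FALSE)
      else data.frame(defect = character(), reaction = character(),
                      detected_by = character()),
    media = list(
      glucose_ammonium = medium_spec(
        EX_glc__D_e = c(-10, 1000), EX_nh4_e = c(-1000, 1000),
        EX_n2_e = c(0, 1000), EX_o2_e = c(-1000, 1000),
        EX_co2_e = c(-1000, 1000), EX_h2_e = c(-1000, 1000),
        EX_h_e = c(-1000, 1000), EX_h2o_e = c(-1000, 1000),
        EX_pi_e = c(-1000, 1000)),
      glucose_n2 = medium_spec(
        EX_glc__D_e = c(-10, 1000), EX_nh4_e = c(0, 1000),
        EX_n2_e = c(-1000, 1000), EX_o2_e = c(-1000, 1000),
        EX_co2_e = c(-1000, 1000), EX_h2_e = c(-1000, 1000),
        EX_h_e = c(-1000, 1000), EX_h2o_e = c(-1000, 1000),
        EX_pi_e = c(-1000, 1000))))
  list(model = model, manifest = manifest)
}

#' Generate a Biolog-style plate with ground-truth calls
#'
#' Draws \code{n_growers} sources from the model's connectable sources of
#' the requested role (positive ground truth: the network can assimilate
#' them) and fills the remaining wells with declared-but-disconnected decoy
#' metabolites (negative ground truth: the exchange exists but no
#' transporter does, emulating plate compounds present in a reconstruction
#' that cannot be metabolised). Sampling is deterministic under the seed.
#'
#' @param toy result of [make_toy_diazotroph()] (model + manifest).
#' @param n_sources number of wells.
#' @param n_growers number of growth-supporting wells (<= n_sources).
#' @param role \code{"carbon"} or \code{"nitrogen"}.
#' @param seed RNG seed.
#' @param plate_id plate label written to the layout.
#' @param dir optional directory; when given, \code{plate.csv} and
#'   \code{calls.csv} are written there.
#' @return list with \code{plate} (well, source_metabolite_id, role,
#'   plate_id), \code{calls} (well, grew) and the file paths when written.
#' @export
make_plate <- function(toy, n_sources = 12, n_growers = 8,
                       role = c("carbon", "nitrogen"), seed = 1,
                       plate_id = "PM1", dir = NULL) {
  role <- match.arg(role)
  stopifnot(n_growers <= n_sources)
  manifest <- toy$manifest
  pool_pos <- if (role == "carbon") manifest$carbon_sources
              else manifest$nitrogen_sources
  pool_neg <- manifest$decoy_sources
  if (n_growers > length(pool_pos))
    stop("model has only ", length(pool_pos), " connectable ", role,
         " sources")
  if (n_sources - n_growers > length(pool_neg))
    stop("not enough decoy sources for ", n_sources - n_growers,
         " negative wells")
  .with_seed(seed, {
    pos <- sort(sample(pool_pos, n_growers))
    neg <- sort(sample(pool_neg, n_sources - n_growers))
    wells <- sample(c(pos, neg))
    plate <- data.frame(
      well = sprintf("%s%02d", substr(plate_id, 1, 1), seq_along(wells)),
      source_metabolite_id = wells,
      role = role, plate_id = plate_id, stringsAsFactors = FALSE)
    calls <- data.frame(well = plate$well,
                        grew = as.integer(wells %in% pos),
                        stringsAsFactors = FALSE)
    out <- list(plate = plate, calls = calls)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      out$plate_path <- file.path(dir, "plate.csv")
      out$calls_path <- file.path(dir, "calls.csv")
      utils::write.csv(plate, out$plate_path, row.names = FALSE, quote = FALSE)
      utils::write.csv(calls, out$calls_path, row.names = FALSE, quote = FALSE)
    }
    out
  })
}

#' Generate a synthetic proteome of known amino-acid composition
#'
#' Residues are drawn i.i.d. from \code{composition} (multinomial), protein
#' lengths from a Poisson around \code{mean_length}; the realised
#' composition is returned alongside so recovery can be tested against the
#' generating truth.
#'
#' @param composition named amino-acid fractions (one-letter codes, sum 1).
#' @param n_proteins,mean_length proteome shape.
#' @param seed RNG seed.
#' @param path optional FASTA output path.
#' @return list with \code{sequences} (named character vector),
#'   \code{target_composition}, \code{realized_composition} and
#'   \code{path} when written.
#' @export
make_proteome <- function(composition, n_proteins = 100, mean_length = 300,
                          seed = 1, path = NULL) {
  if (abs(sum(composition) - 1) > 1e-8)
    stop("composition fractions must sum to 1")
  unknown <- setdiff(names(composition), names(aa_residue_masses))
  if (length(unknown)) stop("unknown amino acids: ",
                            paste(unknown, collapse = ", "))
  .with_seed(seed, {
    lens <- pmax(1L, stats::rpois(n_proteins, mean_length))
    seqs <- vapply(lens, function(L)
      paste(sample(names(composition), L, replace = TRUE,
                   prob = composition), collapse = ""), "")
    names(seqs) <- sprintf("protein_%04d", seq_along(seqs))
    res <- table(factor(strsplit(paste(seqs, collapse = ""), "")[[1]],
                        levels = names(aa_residue_masses)))
    realized <- as.numeric(res) / sum(res)
    names(realized) <- names(aa_residue_masses)
    out <- list(sequences = seqs, target_composition = composition,
                realized_composition = realized)
    if (!is.null(path)) {
      wrap60 <- function(s) {
        starts <- seq(1L, nchar(s), 60L)
        paste(substring(s, starts, pmin(starts + 59L, nchar(s))),
              collapse = "\n")
      }
      writeLines(paste0(">", names(seqs), "\n",
                        vapply(seqs, wrap60, "")), path)
      out$path <- path
    }
    out
  })
}

#' Generate a homology hit table spanning the curation thresholds
#'
#' Emits hits stratified over all eight accept/reject combinations of the
#' three criteria (identity >= 40, e-value <= 1e-4, coverage >= 85),
#' including an exact-boundary row (40.0, 1e-4, 85) which must be accepted
#' under the inclusive thresholds. The expected accept set travels as a
#' sidecar.
#'
#' @param n_hits total rows (>= 8; the stratification cycles).
#' @param seed RNG seed for the within-stratum jitter and row shuffle.
#' @param path optional TSV output path.
#' @return list with \code{hits} (data.frame), \code{expected_accepted}
#'   (qseqid values that pass the filter) and \code{path} when written.
#' @export
make_homology_table <- function(n_hits = 24, seed = 1, path = NULL) {
  stopifnot(n_hits >= 8)
  .with_seed(seed, {
    combos <- expand.grid(id_ok = c(TRUE, FALSE), ev_ok = c(TRUE, FALSE),
                          cov_ok = c(TRUE, FALSE))
    rows <- lapply(seq_len(n_hits), function(i) {
      k <- ((i - 1L) %% nrow(combos)) + 1L
      co <- combos[k, ]
      data.frame(
        qseqid = sprintf("tmpl_%03d", i),
        sseqid = sprintf("AVIN_%05d", sample.int(99999, 1)),
        pident = if (i == 1L) 40.0 else if (co$id_ok)
          round(stats::runif(1, 40, 100), 1) else
          round(stats::runif(1, 5, 39.9), 1),
        evalue = if (i == 1L) 1e-4 else if (co$ev_ok)
          signif(10^stats::runif(1, -50, -4.05), 3) else
          signif(10^stats::runif(1, -3.9, 1), 3),
        qcovs = if (i == 1L) 85 else if (co$cov_ok)
          round(stats::runif(1, 85, 100)) else
          round(stats::runif(1, 10, 84)),
        accepted = i == 1L || (co$id_ok && co$ev_ok && co$cov_ok),
        stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, rows)[sample.int(n_hits), , drop = FALSE]
    rownames(hits) <- NULL
    expected <- hits$qseqid[hits$accepted]
    hits$accepted <- NULL
    out <- list(hits = hits, expected_accepted = expected)
    if (!is.null(path)) {
      utils::write.table(hits, path, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      out$path <- path
    }
    out
  })
}
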