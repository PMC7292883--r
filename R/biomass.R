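## Biomass objective construction from proteome amino-acid composition.
## The protein share of dry weight (default 55%) is distributed over the 20
## amino acids proportionally to their molar frequency in the proteome,
## using dehydrated residue masses (free amino acid minus one water,
## 18.02 g/mol): polymerised protein is what the mass fraction refers to.

#' Average residue (dehydrated) masses of the 20 standard amino acids
#'
#' One-letter codes; g/mol of the residue as polymerised in protein.
#' @format named numeric vector of length 20.
#' @export
aa_residue_masses <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)

## BiGG-style cytoplasmic metabolite ids of the free amino acids
.aa_met_ids <- c(
  A = "ala__L_c", R = "arg__L_c", N = "asn__L_c", D = "asp__L_c",
  C = "cys__L_c", E = "glu__L_c", Q = "gln__L_c", G = "gly_c",
  H = "his__L_c", I = "ile__L_c", L = "leu__L_c", K = "lys__L_c",
  M = "met__L_c", F = "phe__L_c", P = "pro__L_c", S = "ser__L_c",
  T = "thr__L_c", W = "trp__L_c", Y = "tyr__L_c", V = "val__L_c")

#' Amino-acid molar frequencies of a proteome
#'
#' Residues are pooled across all proteins (each protein counted once,
#' unweighted by expression: the theoretical genome-encoded abundance).
#' Ambiguity/noncanonical codes (X, B, Z, U, J, O and stops) are skipped
#' with a warning.
#'
#' @param proteome a FASTA file path, a character vector of sequences, or a
#'   \code{Biostrings::AAStringSet}.
#' @return named numeric vector over the 20 one-letter codes summing to 1.
#' @examples
#' aa_frequencies(c("GA", "AG"))
#' @export
aa_frequencies <- function(proteome) {
  if (is.character(proteome) && length(proteome) == 1L && file.exists(proteome))
    proteome <- Biostrings::readAAStringSet(proteome)
  seqs <- as.character(proteome)
  if (length(seqs) == 0L) stop("empty proteome")
  all_res <- strsplit(paste(toupper(seqs), collapse = ""), "")[[1]]
  standard <- names(aa_residue_masses)
  bad <- !(all_res %in% standard)
  if (any(bad)) {
    warning("skipping ", sum(bad), " non-standard residues (",
            paste(unique(all_res[bad]), collapse = ", "), ")")
    all_res <- all_res[!bad]
  }
  if (length(all_res) == 0L) stop("no standard residues in proteome")
  counts <- table(factor(all_res, levels = standard))
  freqs <- as.numeric(counts) / sum(counts)
  stats::setNames(freqs, standard)
}

#' Build a biomass objective function from amino-acid frequencies
#'
#' Each amino acid receives the stoichiometric coefficient
#' \deqn{c_a = 1000 \, f_{prot} \, f_a / \sum_b f_b m_b}
#' in mmol/gDW, where \eqn{f_{prot}} is the protein mass fraction of dry
#' weight (default 0.55), \eqn{f_a} the molar frequency and \eqn{m_a} the
#' residue mass; by construction \eqn{\sum_a c_a m_a / 1000 = f_{prot}}
#' exactly. Non-protein constituents (nucleotides, lipids, the ATP/GTP
#' polymerisation cost) are copied unchanged from a template biomass
#' reaction.
#'
#' @param frequencies amino-acid molar fractions (must sum to 1, 1e-6).
#' @param protein_mass_fraction protein share of dry weight (g/gDW).
#' @param template_bof optional [reaction()] (or named stoichiometry
#'   vector) whose non-amino-acid entries are passed through.
#' @param id reaction id of the generated objective.
#' @param biomass_met optional product metabolite id credited with +1 unit
#'   of biomass; omitted by default (growth is then the reaction flux).
#' @return list with \code{composition} (data.frame amino_acid, met_id,
#'   coefficient, residue_mass), \code{protein_mass_fraction} and
#'   \code{reaction} (the assembled biomass [reaction()], consuming amino
#'   acids with negative coefficients).
#' @export
build_bof <- function(frequencies, protein_mass_fraction = 0.55,
                      template_bof = NULL, id = "BIOMASS",
                      biomass_met = NULL) {
  unknown <- setdiff(names(frequencies), names(aa_residue_masses))
  if (length(unknown))
    stop("unknown amino acids: ", paste(unknown, collapse = ", "))
  if (abs(sum(frequencies) - 1) > 1e-6)
    stop("frequencies must be normalised (sum to 1); got ", sum(frequencies))
  if (protein_mass_fraction < 0 || protein_mass_fraction > 1)
    stop("protein_mass_fraction must lie in [0, 1]")
  f <- stats::setNames(rep(0, 20), names(aa_residue_masses))
  f[names(frequencies)] <- frequencies
  mean_res_mass <- sum(f * aa_residue_masses)
  coeff <- if (protein_mass_fraction == 0) f * 0 else
    1000 * protein_mass_fraction * f / mean_res_mass
  comp <- data.frame(amino_acid = names(f),
                     met_id = unname(.aa_met_ids[names(f)]),
                     coefficient = unname(coeff),
                     residue_mass = unname(aa_residue_masses[names(f)]),
                     stringsAsFactors = FALSE)
  sto <- stats::setNames(-coeff[coeff > 0], .aa_met_ids[names(coeff)[coeff > 0]])
  if (!is.null(template_bof)) {
    tmpl <- if (inherits(template_bof, "model_reaction")) template_bof$stoich
            else template_bof
    keep <- !(names(tmpl) %in% .aa_met_ids)
    sto <- c(sto, tmpl[keep])
  }
  if (!is.null(biomass_met)) sto[biomass_met] <- 1
  if (length(sto) == 0L)
    stop("degenerate biomass reaction: no constituents (zero protein ",
         "fraction and no template)")
  list(composition = comp,
       protein_mass_fraction = protein_mass_fraction,
       reaction = reaction(id, sto, lb = 0, ub = 1000,
                           name = "biomass objective",
                           subsystem = "Biomass and maintenance functions",
                           pseudo = TRUE))
}

#' Derive an alginate-augmented second biomass objective
#'
#' Copies the model's biomass reaction and adds consumption of periplasmic
#' alginate (mannuronate monomer units) at the given coefficient, so that
#' growth and alginate formation are coupled. The original objective is
#' retained in the model; exactly one objective is active per simulation.
#'
#' @param model a \code{metabolic_model} containing periplasmic alginate.
#' @param alginate_coefficient mmol alginate monomer per gDW biomass.
#' @param bof_id id of the biomass reaction to augment (default: the
#'   model's objective).
#' @param alginate_met periplasmic alginate metabolite id.
#' @param new_id id of the generated second objective.
#' @param activate set the new reaction as the active objective.
#' @return the extended model; the new reaction id in attribute
#'   \code{"bof2_id"}.
#' @export
build_alginate_bof <- function(model, alginate_coefficient,
                               bof_id = model$objective,
                               alginate_met = "alg_p",
                               new_id = paste0(bof_id, "_alg"),
                               activate = TRUE) {
  if (!alginate_met %in% model$metabolites$id)
    .validation_error(paste("periplasmic alginate metabolite absent:",
                            alginate_met))
  if (is.null(bof_id) || !bof_id %in% names(model$reactions))
    stop("biomass reaction not found: ", bof_id)
  if (alginate_coefficient < 0) stop("alginate_coefficient must be >= 0")
  bof <- model$reactions[[bof_id]]
  sto <- bof$stoich
  sto[alginate_met] <- (if (alginate_met %in% names(sto)) sto[[alginate_met]] else 0) -
    alginate_coefficient
  sto <- sto[sto != 0]
  r2 <- reaction(new_id, sto, lb = 0, ub = 1000,
                 name = "biomass objective with alginate",
                 subsystem = bof$subsystem, pseudo = TRUE)
  model <- add_reaction(model, r2)
  if (activate) model <- set_objective(model, new_id)
  attr(model, "bof2_id") <- new_id
  model
}
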