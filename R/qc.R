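## Reconstruction quality control: element/charge balance audit,
## closed-exchange energy-cycle detection and GPR-driven deletion screens.

#' Element and charge balance audit
#'
#' For every internal (non-boundary, non-pseudo) reaction the signed atom
#' count of each element is summed over the stoichiometry; a reaction is
#' balanced iff every element and the net charge balance to exactly zero.
#' Boundary and biomass pseudo-reactions are inherently unbalanced and are
#' skipped (listed separately); reactions touching a metabolite without a
#' formula are flagged unauditable rather than silently passed. Imbalances
#' restricted to protons and/or water are additionally flagged \code{minor},
#' since transport reactions legitimately move protons across membranes.
#'
#' @param model a \code{metabolic_model}.
#' @param tol exact-zero tolerance on atom counts.
#' @return object of class \code{balance_report}: data.frame
#'   (\code{reaction_id}, \code{balanced}, \code{minor},
#'   \code{max_imbalance}), plus \code{imbalances} (per-reaction named
#'   vectors incl. \code{charge}), \code{skipped} and \code{unauditable}.
#' @export
element_balance <- function(model, tol = 1e-9) {
  E <- element_matrix(model)
  charge <- stats::setNames(model$metabolites$charge, model$metabolites$id)
  skipped <- character(0); unauditable <- character(0)
  rows <- list(); imb <- list()
  for (r in model$reactions) {
    if (is_boundary(r) || r$pseudo) { skipped <- c(skipped, r$id); next }
    mets <- names(r$stoich)
    if (any(is.na(E[1, mets])) || any(is.na(charge[mets]))) {
      unauditable <- c(unauditable, r$id); next
    }
    net <- as.numeric(E[, mets, drop = FALSE] %*% r$stoich)
    names(net) <- rownames(E)
    net <- c(net, charge = sum(charge[mets] * r$stoich))
    bal <- all(abs(net) <= tol)
    nonzero <- names(net)[abs(net) > tol]
    minor <- !bal && all(nonzero %in% c("H", "O", "charge"))
    imb[[r$id]] <- net
    rows[[r$id]] <- data.frame(reaction_id = r$id, balanced = bal,
                               minor = minor,
                               max_imbalance = max(abs(net)),
                               stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(reaction_id = character(), balanced = logical(),
               minor = logical(), max_imbalance = numeric())
  rownames(tab) <- NULL
  structure(list(table = tab, imbalances = imb,
                 skipped = skipped, unauditable = unauditable),
            class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  n <- nrow(x$table)
  cat("<balance_report> ", sum(x$table$balanced), "/", n,
      " audited reactions balanced; ", length(x$skipped),
      " boundary/pseudo skipped; ", length(x$unauditable),
      " unauditable\n", sep = "")
  bad <- x$table[!x$table$balanced, , drop = FALSE]
  if (nrow(bad)) print(bad)
  invisible(x)
}

.currency_species <- list(
  atp   = list(diss = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
               need = c("atp_c", "adp_c", "pi_c", "h2o_c", "h_c")),
  nadh  = list(diss = c(nadh_c = -1, nad_c = 1, h_c = 1),
               need = c("nadh_c", "nad_c", "h_c")),
  nadph = list(diss = c(nadph_c = -1, nadp_c = 1, h_c = 1),
               need = c("nadph_c", "nadp_c", "h_c")))

#' Closed-exchange energy-cycle detection
#'
#' With every boundary reaction closed (bounds 0, 0), a temporary
#' dissipation reaction for the currency couple is added (ATP + H2O ->
#' ADP + Pi + H+ for ATP; NAD(P)H -> NAD(P)+ + H+ with electrons implicit
#' for the nicotinamide couples) and its flux maximised. Any positive
#' optimum means the network can generate the currency from nothing: an
#' energy-generating cycle. The report lists the dissipation optimum and
#' the reactions carrying flux in the offending cycle.
#'
#' @param model a \code{metabolic_model}.
#' @param currency \code{"atp"}, \code{"nadh"} or \code{"nadph"}.
#' @param tol pass threshold on the dissipation flux.
#' @return object of class \code{energy_cycle_report} with fields
#'   \code{currency}, \code{dissipation}, \code{cycle_reactions},
#'   \code{pass}.
#' @export
energy_cycle_check <- function(model, currency = c("atp", "nadh", "nadph"),
                               tol = 1e-6) {
  currency <- match.arg(currency)
  spec <- .currency_species[[currency]]
  missing <- setdiff(spec$need, model$metabolites$id)
  if (length(missing))
    stop("currency metabolites absent from model: ",
         paste(missing, collapse = ", "))
  for (rid in boundary_ids(model)) {
    model$reactions[[rid]]$lb <- 0
    model$reactions[[rid]]$ub <- 0
  }
  diss_id <- paste0("DISS_", currency)
  model$reactions[[diss_id]] <- reaction(diss_id, spec$diss, lb = 0, ub = 1000,
                                         subsystem = "QC", pseudo = TRUE)
  p <- .fba_matrices(model)
  cc <- as.numeric(p$rids == diss_id)
  sol <- lp_solve(cc, p$S, rep(0, nrow(p$S)), p$lb, p$ub, sense = "max")
  if (sol$status != "optimal")
    stop("energy cycle LP did not solve: ", sol$status)
  support <- p$rids[abs(sol$x) > 1e-6 & p$rids != diss_id]
  structure(list(currency = currency, dissipation = sol$objval,
                 cycle_reactions = support, pass = sol$objval <= tol),
            class = "energy_cycle_report")
}

#' @export
print.energy_cycle_report <- function(x, ...) {
  cat("<energy_cycle_report> ", toupper(x$currency), ": dissipation ",
      format(x$dissipation, digits = 6),
      if (x$pass) " (pass)" else " (FAIL)", "\n", sep = "")
  if (!x$pass)
    cat("  cycle support:", paste(x$cycle_reactions, collapse = ", "), "\n")
  invisible(x)
}

#' Silence reactions whose GPR is inactivated by a gene knock-out
#'
#' @param model a \code{metabolic_model}.
#' @param genes gene ids to knock out.
#' @return the model with bounds (0, 0) on every reaction whose GPR
#'   evaluates inactive.
#' @export
knock_out_genes <- function(model, genes) {
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) stop("unknown genes: ", paste(unknown, collapse = ", "))
  for (r in model$reactions) {
    if (!is.null(r$gpr) && !eval_gpr(r$gpr, knocked = genes)) {
      model$reactions[[r$id]]$lb <- 0
      model$reactions[[r$id]]$ub <- 0
    }
  }
  model
}

#' Single-gene deletion growth screen
#'
#' For each gene, every reaction whose GPR evaluates inactive under the
#' knock-out is silenced and FBA re-run; the original model is untouched.
#' An LP maximum can never increase when constraints are tightened, so each
#' deletion growth is at most the wild-type growth.
#'
#' @param model a \code{metabolic_model}.
#' @param genes genes to screen (default: all model genes).
#' @param medium optional [medium_spec()].
#' @param objective objective reaction id.
#' @return named numeric vector of growth rates (1/h); infeasible knock-outs
#'   report 0.
#' @export
gene_deletion_screen <- function(model, genes = model$genes, medium = NULL,
                                 objective = model$objective) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  vapply(stats::setNames(genes, genes), function(g) {
    sol <- fba(knock_out_genes(model, g), objective)
    if (sol$status == "optimal") sol$objective_value else 0
  }, numeric(1))
}

#' Full quality-control panel
#'
#' Runs the mass-balance audit and the three closed-exchange energy-cycle
#' checks, and classifies dead-end metabolites.
#'
#' @param model a \code{metabolic_model}.
#' @return list with \code{balance}, \code{energy} (one report per
#'   currency), \code{dead_ends}, and an overall \code{pass} flag (balance
#'   clean and all dissipation optima zero; dead ends are reported but do
#'   not fail the panel).
#' @export
qc_suite <- function(model) {
  bal <- element_balance(model)
  energy <- lapply(stats::setNames(names(.currency_species),
                                   names(.currency_species)),
                   function(cur) energy_cycle_check(model, cur))
  de <- classify_dead_ends(model)
  pass <- all(bal$table$balanced) && length(bal$unauditable) == 0L &&
    all(vapply(energy, `[[`, logical(1), "pass"))
  list(balance = bal, energy = energy, dead_ends = de, pass = pass)
}
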