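#' Constraint-based metabolic model container
#'
#' A \code{metabolic_model} bundles metabolites, reactions, genes, the active
#' objective and a compartment dictionary. Metabolite identifiers follow the
#' BiGG convention of a compartment suffix (\code{_c} cytoplasm, \code{_p}
#' periplasm, \code{_e} extracellular space). Exchange and sink reactions are
#' boundary pseudo-reactions touching exactly one metabolite; by convention
#' negative flux through them is uptake and positive flux secretion.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{formula}, \code{charge}, \code{compartment}.
#' @param reactions list of reaction records (see [reaction()]).
#' @param genes character vector of gene ids; defaults to the union of all
#'   GPR leaves.
#' @param objective reaction id of the active objective (usually a biomass
#'   objective function whose flux is the growth rate in 1/h).
#' @param compartments named character vector mapping compartment codes to
#'   names.
#' @param validate run [validate_model()] on the result.
#' @return object of class \code{metabolic_model}.
#' @export
metabolic_model <- function(id, metabolites, reactions, genes = NULL,
                            objective = NULL,
                            compartments = c(c = "cytoplasm",
                                             p = "periplasm",
                                             e = "extracellular space"),
                            validate = TRUE) {
  stopifnot(is.data.frame(metabolites), is.list(reactions))
  metabolites$id <- as.character(metabolites$id)
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_real_
  rownames(metabolites) <- NULL
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (is.null(genes))
    genes <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))
  if (is.null(genes)) genes <- character()
  m <- structure(list(id = id,
                      metabolites = metabolites,
                      reactions = reactions,
                      genes = genes,
                      objective = objective,
                      compartments = compartments),
                 class = "metabolic_model")
  if (validate) validate_model(m)
  m
}

#' Build a reaction record
#'
#' @param id reaction identifier.
#' @param stoich named numeric vector of stoichiometric coefficients
#'   (negative = substrate, positive = product), in mmol/gDW/h flux units.
#' @param lb,ub flux bounds (mmol/gDW/h).
#' @param name human-readable name.
#' @param subsystem pathway-level grouping label.
#' @param gpr GPR tree (or NULL for an orphan reaction).
#' @param provenance one of \code{"native"}, \code{"template:<model-id>"},
#'   \code{"gapfilled"}, \code{"orphan"}.
#' @param pseudo logical; TRUE for pseudo-reactions (biomass objectives)
#'   that are exempt from the mass-balance audit.
#' @param exogenous_only logical; TRUE once curation has established that
#'   the association involved only template-organism genes.
#' @return a reaction record (plain list of class \code{model_reaction}).
#' @export
reaction <- function(id, stoich, lb = -1000, ub = 1000, name = id,
                     subsystem = "", gpr = NULL, provenance = "native",
                     pseudo = FALSE, exogenous_only = FALSE) {
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0L) stop("reaction '", id, "' has empty stoichiometry")
  if (is.null(names(stoich)) || any(!nzchar(names(stoich))))
    stop("reaction '", id, "' stoichiometry must be fully named")
  if (lb > ub) stop("reaction '", id, "': lower_bound > upper_bound")
  structure(list(id = id, name = name, stoich = stoich,
                 lb = lb, ub = ub, subsystem = subsystem, gpr = gpr,
                 provenance = provenance, pseudo = isTRUE(pseudo),
                 exogenous_only = isTRUE(exogenous_only)),
            class = "model_reaction")
}

.validation_error <- function(msg) {
  stop(structure(class = c("model_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Validate a metabolic model's structural invariants
#'
#' Checks: unique metabolite ids; compartment suffix agreement; parsable
#' formulas; reaction bounds ordered; every stoichiometry key resolving to a
#' metabolite; GPR leaves contained in the gene list; boundary reactions
#' touching exactly one metabolite; the objective reaction existing.
#' Violations raise a condition of class \code{model_validation_error}.
#'
#' @param model a \code{metabolic_model}.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id))
    .validation_error(paste("duplicated metabolite ids:",
                            paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  if (!all(mets$compartment %in% names(model$compartments)))
    .validation_error(paste("unknown compartment for:",
      paste(mets$id[!mets$compartment %in% names(model$compartments)], collapse = ", ")))
  suffix <- sub("^.*_", "", mets$id)
  bad <- suffix != mets$compartment
  if (any(bad))
    .validation_error(paste("metabolite id suffix does not match compartment:",
                            paste(mets$id[bad], collapse = ", ")))
  for (i in seq_len(nrow(mets)))
    if (!is.na(mets$formula[i])) parse_formula(mets$formula[i])
  rids <- names(model$reactions)
  if (anyDuplicated(rids))
    .validation_error("duplicated reaction ids")
  for (r in model$reactions) {
    if (r$lb > r$ub)
      .validation_error(paste0("reaction '", r$id, "': lower_bound > upper_bound"))
    missing <- setdiff(names(r$stoich), mets$id)
    if (length(missing))
      .validation_error(paste0("reaction '", r$id, "' references unknown metabolites: ",
                               paste(missing, collapse = ", ")))
    extra <- setdiff(gpr_genes(r$gpr), model$genes)
    if (length(extra))
      .validation_error(paste0("reaction '", r$id, "' GPR references genes missing from the gene list: ",
                               paste(extra, collapse = ", ")))
  }
  if (!is.null(model$objective) && !all(model$objective %in% rids))
    .validation_error(paste("objective reaction not in model:", model$objective))
  invisible(model)
}

#' Is a reaction a boundary (exchange/sink/demand) pseudo-reaction?
#'
#' Boundary reactions touch exactly one metabolite; they move mass across
#' the system boundary and are exempt from mass-balance accounting.
#'
#' @param rxn a reaction record.
#' @return logical scalar.
#' @export
is_boundary <- function(rxn) length(rxn$stoich) == 1L

#' Ids of all boundary reactions of a model
#' @param model a \code{metabolic_model}.
#' @return character vector.
#' @export
boundary_ids <- function(model) {
  names(model$reactions)[vapply(model$reactions, is_boundary, logical(1))]
}

#' Stoichiometric matrix of a model
#'
#' @param model a \code{metabolic_model}.
#' @param sparse return a \code{Matrix::dgCMatrix} (default) or base matrix.
#' @return metabolites x reactions matrix with dimnames; entry (i, j) is the
#'   signed coefficient of metabolite i in reaction j.
#' @export
stoich_matrix <- function(model, sparse = TRUE) {
  mets <- model$metabolites$id
  rids <- names(model$reactions)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rids)) {
    s <- model$reactions[[j]]$stoich
    ii <- c(ii, match(names(s), mets))
    jj <- c(jj, rep.int(j, length(s)))
    xx <- c(xx, as.numeric(s))
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(mets), length(rids)),
                            dimnames = list(mets, rids))
  if (sparse) S else as.matrix(S)
}

#' Construct a growth-medium specification
#'
#' A medium maps exchange-reaction ids to (lower, upper) flux bounds in
#' mmol/gDW/h; uptake is encoded as a negative lower bound.
#'
#' @param ... named length-2 numeric vectors, e.g.
#'   \code{EX_glc__D_e = c(-10, 1000)}.
#' @param .list alternatively, a named list of such vectors.
#' @return object of class \code{medium_spec}.
#' @export
medium_spec <- function(..., .list = NULL) {
  entries <- if (is.null(.list)) list(...) else .list
  if (length(entries) && (is.null(names(entries)) || any(!nzchar(names(entries)))))
    stop("medium entries must be named by exchange reaction id")
  entries <- lapply(entries, function(b) {
    stopifnot(is.numeric(b), length(b) == 2L, b[1] <= b[2])
    as.numeric(b)
  })
  structure(entries, class = "medium_spec")
}

#' Apply a medium to a model
#'
#' Bounds of the referenced exchange reactions are replaced. Uptake through
#' every *unreferenced* boundary reaction is closed (lower bound raised to
#' 0); secretion stays open. Internal reaction bounds are untouched.
#'
#' @param model a \code{metabolic_model}.
#' @param medium a [medium_spec()] (a plain named list is accepted).
#' @return the constrained model.
#' @export
apply_medium <- function(model, medium) {
  bids <- boundary_ids(model)
  unknown <- setdiff(names(medium), names(model$reactions))
  if (length(unknown))
    stop("medium references unknown exchange reactions: ",
         paste(unknown, collapse = ", "))
  not_boundary <- setdiff(names(medium), bids)
  if (length(not_boundary))
    stop("medium may only reference exchange/sink reactions; offending: ",
         paste(not_boundary, collapse = ", "))
  for (rid in bids) {
    if (rid %in% names(medium)) {
      b <- medium[[rid]]
      model$reactions[[rid]]$lb <- b[1]
      model$reactions[[rid]]$ub <- b[2]
    } else {
      model$reactions[[rid]]$lb <- max(model$reactions[[rid]]$lb, 0)
    }
  }
  model
}

#' Add a reaction to a model
#' @param model a \code{metabolic_model}.
#' @param rxn a [reaction()] record; its metabolites must exist unless
#'   supplied through \code{new_metabolites}.
#' @param new_metabolites optional data.frame of metabolites to add first.
#' @return the extended model.
#' @export
add_reaction <- function(model, rxn, new_metabolites = NULL) {
  if (!is.null(new_metabolites)) {
    keep <- !new_metabolites$id %in% model$metabolites$id
    model$metabolites <- rbind(model$metabolites, new_metabolites[keep, , drop = FALSE])
  }
  if (rxn$id %in% names(model$reactions))
    stop("reaction '", rxn$id, "' already present")
  model$reactions[[rxn$id]] <- rxn
  model$genes <- union(model$genes, gpr_genes(rxn$gpr))
  validate_model(model)
  model
}

#' Drop reactions from a model
#' @param model a \code{metabolic_model}.
#' @param ids reaction ids to remove.
#' @return the reduced model.
#' @export
remove_reactions <- function(model, ids) {
  missing <- setdiff(ids, names(model$reactions))
  if (length(missing)) stop("unknown reactions: ", paste(missing, collapse = ", "))
  model$reactions <- model$reactions[setdiff(names(model$reactions), ids)]
  if (!is.null(model$objective)) model$objective <- setdiff(model$objective, ids)
  if (length(model$objective) == 0L) model$objective <- NULL
  model
}

#' Set the active objective reaction
#' @param model a \code{metabolic_model}.
#' @param id reaction id.
#' @return the model.
#' @export
set_objective <- function(model, id) {
  if (!id %in% names(model$reactions)) stop("unknown reaction: ", id)
  model$objective <- id
  model
}

#' Summary counts of a model
#'
#' @param model a \code{metabolic_model}.
#' @return list with reaction, metabolite, gene and orphan-reaction counts
#'   plus a reactions-per-subsystem table (which sums to the reaction count).
#' @export
summarize_model <- function(model) {
  subsys <- vapply(model$reactions, function(r)
    if (nzchar(r$subsystem)) r$subsystem else "(unassigned)", "")
  orphan <- vapply(model$reactions, function(r)
    is.null(r$gpr) && !is_boundary(r), logical(1))
  structure(list(id = model$id,
                 n_reactions = length(model$reactions),
                 n_metabolites = nrow(model$metabolites),
                 n_genes = length(model$genes),
                 n_orphan_reactions = sum(orphan),
                 subsystems = sort(table(subsys), decreasing = TRUE)),
            class = "model_summary")
}

#' @export
print.model_summary <- function(x, ...) {
  cat("Model ", x$id, ": ", x$n_reactions, " reactions, ",
      x$n_metabolites, " metabolites, ", x$n_genes, " genes (",
      x$n_orphan_reactions, " orphan reactions)\n", sep = "")
  print(x$subsystems)
  invisible(x)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "  reactions: ", length(x$reactions),
      "  genes: ", length(x$genes), "\n",
      "  objective: ", if (is.null(x$objective)) "(none)" else x$objective,
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) summarize_model(object)

#' @export
print.model_reaction <- function(x, ...) {
  lhs <- x$stoich[x$stoich < 0]; rhs <- x$stoich[x$stoich > 0]
  fmt <- function(s) paste(ifelse(abs(s) == 1, names(s),
                                  paste(abs(s), names(s))), collapse = " + ")
  arrow <- if (x$lb < 0 && x$ub > 0) "<=>" else if (x$ub > 0) "-->" else "<--"
  cat(x$id, ": ", fmt(lhs), " ", arrow, " ", fmt(rhs),
      "  [", x$lb, ", ", x$ub, "]\n", sep = "")
  invisible(x)
}
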