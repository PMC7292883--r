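## Flux balance analysis layer. The LP is max/min c'v subject to S v = 0 and
## lb <= v <= ub; fluxes in mmol/gDW/h, a biomass objective's flux in 1/h.
## Unconstrained bounds are capped at +/-1000 mmol/gDW/h, the usual COBRA
## convention, which keeps every LP bounded.

.FLUX_CAP <- 1000

.fba_matrices <- function(model) {
  S <- as.matrix(stoich_matrix(model, sparse = FALSE))
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  lb <- pmax(lb, -.FLUX_CAP); ub <- pmin(ub, .FLUX_CAP)
  list(S = S, lb = lb, ub = ub, rids = names(model$reactions))
}

.flux_distribution <- function(fluxes, objective_value, objective_id, status) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 objective_id = objective_id, status = status),
            class = "flux_distribution")
}

#' Flux balance analysis
#'
#' Solves the linear program optimise \code{sense(v_obj)} subject to
#' steady-state mass balance \code{S v = 0} and the model's flux bounds.
#' The optimum of a biomass objective is the predicted growth rate (1/h).
#'
#' @param model a \code{metabolic_model}.
#' @param objective reaction id to optimise; defaults to the model's active
#'   objective.
#' @param sense \code{"max"} (default) or \code{"min"}.
#' @param medium optional [medium_spec()] applied before solving.
#' @return a \code{flux_distribution}: named flux vector, objective value,
#'   and solver status (\code{"optimal"}, \code{"infeasible"} or
#'   \code{"unbounded"}). No flux vector is returned for non-optimal status.
#' @examples
#' toy <- make_toy_diazotroph()
#' sol <- fba(toy$model)
#' sol$objective_value
#' @export
fba <- function(model, objective = model$objective, sense = c("max", "min"),
                medium = NULL) {
  sense <- match.arg(sense)
  if (is.null(objective)) stop("model has no objective reaction; supply one")
  if (!objective %in% names(model$reactions))
    stop("objective reaction not in model: ", objective)
  if (!is.null(medium)) model <- apply_medium(model, medium)
  p <- .fba_matrices(model)
  cc <- as.numeric(p$rids == objective)
  sol <- lp_solve(cc, p$S, rep(0, nrow(p$S)), p$lb, p$ub, sense = sense)
  if (sol$status != "optimal")
    return(.flux_distribution(NULL, NA_real_, objective, sol$status))
  .flux_distribution(stats::setNames(sol$x, p$rids), sol$objval, objective,
                     "optimal")
}

#' Parsimonious FBA
#'
#' Fixes the objective at its FBA optimum, then minimises the total absolute
#' flux (sum over |v|, by splitting every flux into forward and reverse
#' parts). FBA optima are typically degenerate; pFBA selects a single,
#' reproducible representative, which downstream flux partitioning and
#' flux-map comparisons rely on.
#'
#' @inheritParams fba
#' @return a \code{flux_distribution} whose objective value equals the FBA
#'   optimum and whose \code{sum_abs_flux} attribute is minimal.
#' @export
pfba <- function(model, objective = model$objective, medium = NULL) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  base <- fba(model, objective)
  if (base$status != "optimal") return(base)
  p <- .fba_matrices(model)
  n <- length(p$rids)
  # v = f - r, f in [max(lb,0), max(ub,0)], r in [max(-ub,0), max(-lb,0)]
  A <- cbind(p$S, -p$S)
  cobj <- as.numeric(p$rids == objective)
  A <- rbind(A, c(cobj, -cobj))       # pin the optimum
  rhs <- c(rep(0, nrow(p$S)), base$objective_value)
  lb2 <- c(pmax(p$lb, 0), pmax(-p$ub, 0))
  ub2 <- c(pmax(p$ub, 0), pmax(-p$lb, 0))
  sol <- lp_solve(rep(1, 2 * n), A, rhs, lb2, ub2, sense = "min")
  if (sol$status != "optimal")
    return(.flux_distribution(NULL, NA_real_, objective, sol$status))
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  out <- .flux_distribution(stats::setNames(v, p$rids),
                            base$objective_value, objective, "optimal")
  attr(out, "sum_abs_flux") <- sol$objval
  out
}

#' Feasible flux range of a single reaction
#'
#' @param model a \code{metabolic_model}.
#' @param rid reaction id.
#' @param medium optional medium applied first.
#' @return c(min, max) over the feasible region.
#' @export
flux_range <- function(model, rid, medium = NULL) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  lo <- fba(model, rid, sense = "min")
  hi <- fba(model, rid, sense = "max")
  c(min = if (lo$status == "optimal") lo$objective_value else NA_real_,
    max = if (hi$status == "optimal") hi$objective_value else NA_real_)
}

#' Blocked reactions under a medium
#'
#' A reaction is blocked when its maximum and minimum feasible flux are both
#' zero (|.| <= 1e-9): no steady-state flux can traverse it under the given
#' exchange constraints.
#'
#' @param model a \code{metabolic_model}.
#' @param medium optional [medium_spec()].
#' @param tol zero tolerance.
#' @return character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(model, medium = NULL, tol = 1e-9) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  p <- .fba_matrices(model)
  zero <- rep(0, nrow(p$S))
  blocked <- character(0)
  for (j in seq_along(p$rids)) {
    cc <- as.numeric(seq_along(p$rids) == j)
    hi <- lp_solve(cc, p$S, zero, p$lb, p$ub, sense = "max")
    if (hi$status == "optimal" && hi$objval > tol) next
    lo <- lp_solve(cc, p$S, zero, p$lb, p$ub, sense = "min")
    if (lo$status == "optimal" && lo$objval < -tol) next
    if (hi$status == "infeasible") next   # infeasible model: nothing to report
    blocked <- c(blocked, p$rids[j])
  }
  blocked
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> objective ", x$objective_id, " = ",
      format(x$objective_value, digits = 6), " (", x$status, ")\n", sep = "")
  if (!is.null(x$fluxes)) {
    nz <- x$fluxes[abs(x$fluxes) > 1e-9]
    cat("  ", length(nz), " of ", length(x$fluxes),
        " reactions carry flux\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.flux_distribution <- function(x, ...) {
  if (is.null(x$fluxes)) return(data.frame(reaction_id = character(),
                                           flux = numeric()))
  data.frame(reaction_id = names(x$fluxes), flux = unname(x$fluxes),
             stringsAsFactors = FALSE)
}
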