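## Elemental flux partitioning per subsystem, cross-condition correlation,
## and storage-polymer production analysis (alginate secretion, PHB sink).

#' Element throughput of one reaction at a given flux
#'
#' Defined on the product side: |flux| x sum over positive-coefficient
#' entries of coefficient x atoms of the element. For an element-balanced
#' reaction the substrate-side sum is identical, which [element_balance()]
#' audits; the product-side convention makes the definition usable for the
#' biomass pseudo-reaction too.
#'
#' @param model a \code{metabolic_model} (for metabolite formulas).
#' @param rid reaction id.
#' @param flux flux value (mmol/gDW/h).
#' @param element element symbol, typically \code{"C"} or \code{"N"}.
#' @return mmol element/gDW/h (>= 0).
#' @export
element_throughput <- function(model, rid, flux, element = "C") {
  r <- model$reactions[[rid]]
  if (is.null(r)) stop("unknown reaction: ", rid)
  E <- element_matrix(model)
  if (!element %in% rownames(E)) return(0)
  prods <- r$stoich[r$stoich > 0]
  if (length(prods) == 0L) return(0)
  atoms <- E[element, names(prods)]
  if (any(is.na(atoms)))
    stop("reaction '", rid, "' has products without formulas")
  abs(flux) * sum(prods * atoms)
}

#' Partition elemental flux over subsystems
#'
#' Average element throughput of each subsystem's member reactions under a
#' deterministic (pFBA) flux distribution. The mean includes zero-flux
#' members. Transport and exchange subsystems are computed but flagged for
#' exclusion from headline summaries, since their throughput double-counts
#' the uptake of every source.
#'
#' @param model a \code{metabolic_model}.
#' @param flux a \code{flux_distribution} (use [pfba()] so results are
#'   reproducible) or a named flux vector.
#' @param element element symbol.
#' @param exclude subsystem labels flagged as non-headline (matched
#'   case-insensitively as prefixes, so "Transport, inner membrane" is
#'   caught by "transport").
#' @param active_only average over nonzero-flux members instead.
#' @return named numeric vector (subsystem -> mean throughput) with the
#'   excluded labels in attribute \code{"excluded"}.
#' @export
partition_fluxes <- function(model, flux, element = "C",
                             exclude = c("transport", "exchange"),
                             active_only = FALSE) {
  v <- if (inherits(flux, "flux_distribution")) flux$fluxes else flux
  if (is.null(v)) stop("flux distribution has no flux vector")
  E <- element_matrix(model)
  has_el <- element %in% rownames(E)
  th <- vapply(names(model$reactions), function(rid) {
    if (!has_el) return(0)
    r <- model$reactions[[rid]]
    prods <- r$stoich[r$stoich > 0]
    if (length(prods) == 0L) return(0)
    atoms <- E[element, names(prods)]
    if (any(is.na(atoms))) return(NA_real_)
    f <- if (rid %in% names(v)) v[[rid]] else 0
    abs(f) * sum(prods * atoms)
  }, numeric(1))
  subsys <- vapply(model$reactions, function(r)
    if (nzchar(r$subsystem)) r$subsystem else "(unassigned)", "")
  groups <- split(th, subsys)
  avg <- vapply(groups, function(x) {
    x <- x[!is.na(x)]
    if (active_only) x <- x[x > 1e-9]
    if (length(x) == 0L) 0 else mean(x)
  }, numeric(1))
  excl <- names(avg)[vapply(tolower(names(avg)), function(s)
    any(startsWith(s, tolower(exclude))), logical(1))]
  attr(avg, "excluded") <- excl
  avg
}

#' Subsystem x condition element-flux table
#'
#' Runs pFBA for every condition and stacks the subsystem partitions into
#' the matrix consumed by [compare_conditions()].
#'
#' @param model a \code{metabolic_model}.
#' @param conditions list of [screen_condition()]s (all of one nitrogen
#'   mode, typically).
#' @param element element symbol.
#' @param ... passed to [partition_fluxes()].
#' @return matrix subsystem x condition; all-zero columns mark conditions
#'   that did not grow. Attribute \code{"excluded"} carries the non-headline
#'   subsystem labels.
#' @export
partition_table <- function(model, conditions, element = "C", ...) {
  cols <- lapply(conditions, function(cond) {
    med <- build_condition(model, cond)
    if (inherits(med, "screen_exclusion")) return(NULL)
    sol <- pfba(model, medium = med)
    if (sol$status != "optimal") {
      subsys <- vapply(model$reactions, function(r)
        if (nzchar(r$subsystem)) r$subsystem else "(unassigned)", "")
      z <- stats::setNames(rep(0, length(unique(subsys))), sort(unique(subsys)))
      return(z)
    }
    partition_fluxes(model, sol, element, ...)
  })
  keep <- !vapply(cols, is.null, logical(1))
  cols <- cols[keep]
  ids <- vapply(conditions[keep], `[[`, "", "id")
  tab <- do.call(cbind, lapply(cols, function(x) x[sort(names(cols[[1]]))]))
  colnames(tab) <- ids
  attr(tab, "excluded") <- attr(cols[[1]], "excluded")
  tab
}

#' Correlate subsystem flux distributions across nitrogen regimes
#'
#' For each subsystem, the Pearson correlation across conditions between
#' the diazotrophic and non-diazotrophic element-flux vectors; r > 0.9
#' flags a similar distribution. Also reports the global percent change
#' (sum of the diazotrophic table relative to the non-diazotrophic one).
#' Correlations are undefined (NA) when either vector is constant, and are
#' invariant to common positive rescaling of both tables.
#'
#' @param table_diazo,table_nondiazo matrices from [partition_table()] with
#'   identical dimnames.
#' @param similarity_threshold flag threshold on r.
#' @return object of class \code{subsystem_correlation}: data.frame
#'   (\code{subsystem}, \code{r}, \code{similar}) plus
#'   \code{global_percent_change}.
#' @export
compare_conditions <- function(table_diazo, table_nondiazo,
                               similarity_threshold = 0.9) {
  if (!identical(dimnames(table_diazo), dimnames(table_nondiazo)))
    stop("the two tables must share subsystems and conditions")
  r <- vapply(rownames(table_diazo), function(s) {
    x <- table_diazo[s, ]; y <- table_nondiazo[s, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  denom <- sum(table_nondiazo)
  gpc <- if (denom == 0) NA_real_ else
    (sum(table_diazo) - denom) / denom * 100
  structure(list(table = data.frame(subsystem = rownames(table_diazo),
                                    r = unname(r),
                                    similar = unname(!is.na(r) &
                                                     r > similarity_threshold),
                                    stringsAsFactors = FALSE),
                 global_percent_change = gpc),
            class = "subsystem_correlation")
}

#' @export
print.subsystem_correlation <- function(x, ...) {
  cat("<subsystem_correlation> global change ",
      format(x$global_percent_change, digits = 4), "%\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Add an intracellular sink reaction for a storage metabolite
#'
#' The sink \code{SK_<met>}: met -> (nothing), bounds (0, 1000), models
#' accumulation of a storage compound (PHB) that never leaves the cell.
#' Adding an existing sink is a no-op (idempotent).
#'
#' @param model a \code{metabolic_model}.
#' @param met metabolite id.
#' @return the extended model; the sink id in attribute \code{"sink_id"}.
#' @export
add_sink <- function(model, met) {
  if (!met %in% model$metabolites$id) stop("unknown metabolite: ", met)
  sid <- paste0("SK_", met)
  if (!sid %in% names(model$reactions)) {
    model <- add_reaction(model, reaction(sid, stats::setNames(-1, met),
                                          lb = 0, ub = 1000,
                                          name = paste("sink for", met),
                                          subsystem = "Exchange",
                                          pseudo = TRUE))
  }
  attr(model, "sink_id") <- sid
  model
}

#' Growth-coupled production rate of a target product
#'
#' Two-stage LP: growth is maximised first, then pinned to at least
#' \code{growth_fraction} of its optimum while the product flux is
#' maximised. \code{growth_fraction = 1} gives production at maximal
#' growth; \code{0} gives the maximum theoretical yield.
#'
#' @param model a \code{metabolic_model}.
#' @param product exchange or sink reaction id of the product.
#' @param medium optional [medium_spec()].
#' @param growth_fraction in [0, 1].
#' @param objective growth objective id.
#' @return named numeric: \code{mu} (1/h) and \code{production}
#'   (mmol/gDW/h).
#' @export
production_rate <- function(model, product, medium = NULL,
                            growth_fraction = 1, objective = model$objective) {
  stopifnot(growth_fraction >= 0, growth_fraction <= 1)
  if (!product %in% names(model$reactions))
    stop("unknown product reaction: ", product)
  if (!is.null(medium)) model <- apply_medium(model, medium)
  g <- fba(model, objective)
  if (g$status != "optimal")
    return(c(mu = 0, production = 0))
  mu <- g$objective_value
  floor_mu <- growth_fraction * mu * (1 - 1e-9)
  model$reactions[[objective]]$lb <- max(model$reactions[[objective]]$lb,
                                         floor_mu)
  p <- fba(model, product)
  c(mu = mu,
    production = if (p$status == "optimal") p$objective_value else 0)
}

#' Normalise a flux map to an anchor reaction
#'
#' Every flux is scaled by \code{scale / |anchor flux|}, so the anchor maps
#' to +/-100 under the default scale; flux ratios are preserved exactly and
#' re-normalising with the same anchor is idempotent.
#'
#' @param flux a \code{flux_distribution} or named flux vector.
#' @param anchor reaction id with nonzero flux (typically the glucose
#'   exchange).
#' @param scale target magnitude of the anchor.
#' @return named numeric vector of normalised fluxes.
#' @export
normalize_flux_map <- function(flux, anchor, scale = 100) {
  v <- if (inherits(flux, "flux_distribution")) flux$fluxes else flux
  if (!anchor %in% names(v)) stop("anchor reaction not in flux map: ", anchor)
  if (abs(v[[anchor]]) < 1e-12)
    stop("anchor reaction carries zero flux; cannot normalise")
  v * (scale / abs(v[[anchor]]))
}

#' Compare a predicted flux map against a reference map
#'
#' Percent error per shared reaction, |pred - ref| / |ref| x 100; both maps
#' should be normalised to the same anchor first. A zero reference with a
#' zero prediction counts as 0 error; a zero reference with nonzero
#' prediction is flagged infinite. Agreement holds iff the error does not
#' exceed \code{threshold} percent.
#'
#' @param predicted,reference named numeric flux maps.
#' @param threshold agreement threshold in percent.
#' @return object of class \code{flux_comparison}: data.frame
#'   (\code{reaction_id}, \code{predicted}, \code{reference},
#'   \code{percent_error}, \code{agree}) plus counts above/below threshold.
#' @export
compare_flux_maps <- function(predicted, reference, threshold = 20) {
  shared <- intersect(names(predicted), names(reference))
  if (length(shared) == 0L) stop("no shared reactions between the maps")
  pe <- vapply(shared, function(rid) {
    p <- predicted[[rid]]; r <- reference[[rid]]
    if (r == 0) { if (p == 0) 0 else Inf } else abs(p - r) / abs(r) * 100
  }, numeric(1))
  tab <- data.frame(reaction_id = shared,
                    predicted = unname(predicted[shared]),
                    reference = unname(reference[shared]),
                    percent_error = unname(pe),
                    agree = unname(pe <= threshold),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, threshold = threshold,
                 n_agree = sum(tab$agree), n_disagree = sum(!tab$agree)),
            class = "flux_comparison")
}

#' @export
print.flux_comparison <- function(x, ...) {
  cat("<flux_comparison> ", x$n_agree, "/", nrow(x$table),
      " reactions within ", x$threshold, "% of the reference\n", sep = "")
  bad <- x$table[!x$table$agree, , drop = FALSE]
  if (nrow(bad)) print(bad)
  invisible(x)
}
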