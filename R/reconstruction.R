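## Draft-model curation: homology-hit filtering, GPR remapping from template
## genes to target-organism genes, pruning of flux-dead exogenous reactions,
## dead-end classification and parsimony gap-filling.

#' Read a BLAST-style homology hit table
#'
#' Tab-separated with columns \code{qseqid} (template gene), \code{sseqid}
#' (target-organism gene), \code{pident}, \code{evalue}, \code{qcovs}
#' (query coverage percent, BLAST outfmt-6 naming). A header line is
#' detected and honoured; headerless outfmt-6 files are accepted with the
#' columns in that order.
#'
#' @param path TSV file path.
#' @return data.frame of hits.
#' @export
read_homology_hits <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("qseqid", first, fixed = TRUE)
  hits <- utils::read.delim(path, header = has_header,
                            stringsAsFactors = FALSE)
  if (!has_header) {
    if (ncol(hits) < 5L) stop("expected >= 5 columns in '", path, "'")
    names(hits)[1:5] <- c("qseqid", "sseqid", "pident", "evalue", "qcovs")
  }
  need <- c("qseqid", "sseqid", "pident", "evalue", "qcovs")
  missing <- setdiff(need, names(hits))
  if (length(missing)) stop("hit table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (any(hits$pident < 0 | hits$pident > 100) ||
      any(hits$qcovs < 0 | hits$qcovs > 100) || any(hits$evalue < 0))
    stop("homology hits out of range (identity/coverage in [0,100], evalue >= 0)")
  hits
}

#' Filter homology hits on the curation acceptance thresholds
#'
#' A hit is accepted iff percent identity >= \code{min_identity} AND
#' e-value <= \code{max_evalue} AND query coverage >= \code{min_coverage};
#' all three thresholds are inclusive. Defaults are the curation criteria
#' used for the reconstruction: 40\% identity, e-value 1e-4, 85\% coverage.
#'
#' @param hits data.frame as from [read_homology_hits()].
#' @param min_identity,max_evalue,min_coverage inclusive thresholds.
#' @return the accepted subset of \code{hits}.
#' @export
filter_hits <- function(hits, min_identity = 40, max_evalue = 1e-4,
                        min_coverage = 85) {
  keep <- hits$pident >= min_identity & hits$evalue <= max_evalue &
    hits$qcovs >= min_coverage
  hits[keep, , drop = FALSE]
}

#' Best-hit mapping template gene -> target gene
#'
#' Among the accepted hits of each template gene the best is chosen by
#' lowest e-value, ties broken by highest identity and then lexicographic
#' subject id (a deterministic rule; the choice is not dictated by the
#' thresholds themselves).
#'
#' @param hits accepted hits (apply [filter_hits()] first).
#' @return named character vector: template gene id -> target gene id.
#' @export
best_hit_mapping <- function(hits) {
  if (nrow(hits) == 0L) return(stats::setNames(character(0), character(0)))
  picks <- lapply(split(hits, hits$qseqid), function(h) {
    h <- h[order(h$evalue, -h$pident, h$sseqid), , drop = FALSE]
    h$sseqid[1]
  })
  stats::setNames(unlist(picks), names(picks))
}

#' Remap a GPR tree from template genes to target-organism genes
#'
#' Mapped leaves are renamed. Unmapped leaves are removed with boolean
#' simplification: an OR simply loses the leaf, while an AND branch with an
#' unmapped leaf is removed entirely under the default \code{strict} policy
#' (a complex is not asserted catalytically active when a subunit has no
#' homolog); \code{permissive} instead drops only the leaf. An association
#' that vanishes entirely is returned as \code{NULL} with
#' \code{exogenous_only = TRUE}.
#'
#' @param gpr a GPR tree or NULL.
#' @param mapping named character vector (template -> target), typically
#'   from [best_hit_mapping()].
#' @param policy \code{"strict"} (default) or \code{"permissive"}.
#' @return list with \code{gpr} (remapped tree or NULL) and
#'   \code{exogenous_only} (TRUE iff a non-empty association vanished).
#' @export
remap_gpr <- function(gpr, mapping, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  rec <- function(node) {
    if (is.null(node)) return(NULL)
    if (node$kind == "gene") {
      if (node$gene %in% names(mapping)) return(gpr_gene(mapping[[node$gene]]))
      return(NULL)
    }
    kids <- lapply(node$children, rec)
    dropped <- vapply(kids, is.null, logical(1))
    if (node$kind == "and" && policy == "strict" && any(dropped))
      return(NULL)
    kids <- kids[!dropped]
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    .gpr_node(node$kind, kids)
  }
  out <- rec(gpr)
  list(gpr = out, exogenous_only = !is.null(gpr) && is.null(out))
}

#' Remap every GPR of a model
#'
#' Applies [remap_gpr()] reaction-wise; reactions whose association vanished
#' are flagged \code{exogenous_only} and left as orphans pending
#' [prune_exogenous()]. The gene list is rebuilt from the remapped trees.
#'
#' @param model a \code{metabolic_model}.
#' @inheritParams remap_gpr
#' @return the remapped model.
#' @export
remap_model_gprs <- function(model, mapping, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  for (r in model$reactions) {
    res <- remap_gpr(r$gpr, mapping, policy)
    model$reactions[[r$id]]$gpr <- res$gpr
    model$reactions[[r$id]]$exogenous_only <- res$exogenous_only
  }
  model$genes <- unique(unlist(lapply(model$reactions,
                                      function(r) gpr_genes(r$gpr))))
  if (is.null(model$genes)) model$genes <- character()
  validate_model(model)
  model
}

#' Prune flux-dead exogenous reactions
#'
#' A reaction is removed iff it is flagged \code{exogenous_only} (its GPR
#' involved only template-organism genes with no homolog) AND it is blocked
#' under every supplied growth condition. Native orphan reactions are never
#' pruned. The objective optimum of every condition is asserted unchanged
#' (1e-6 relative) after pruning.
#'
#' @param model a \code{metabolic_model}.
#' @param conditions list of [medium_spec()]s representing the experimental
#'   conditions under which flux is probed.
#' @return list with \code{model} (pruned) and \code{removed} (reaction ids).
#' @export
prune_exogenous <- function(model, conditions) {
  stopifnot(length(conditions) >= 1L)
  exo <- names(model$reactions)[vapply(model$reactions, `[[`, logical(1),
                                       "exogenous_only")]
  if (length(exo) == 0L) return(list(model = model, removed = character(0)))
  blocked_everywhere <- exo
  for (med in conditions) {
    if (length(blocked_everywhere) == 0L) break
    b <- blocked_reactions(model, med)
    blocked_everywhere <- intersect(blocked_everywhere, b)
  }
  before <- vapply(conditions, function(med)
    fba(model, medium = med)$objective_value, numeric(1))
  pruned <- if (length(blocked_everywhere))
    remove_reactions(model, blocked_everywhere) else model
  after <- vapply(conditions, function(med)
    fba(pruned, medium = med)$objective_value, numeric(1))
  if (any(abs(after - before) > 1e-6 * pmax(1, abs(before)), na.rm = TRUE))
    stop("pruning changed a condition optimum; refusing to prune")
  list(model = pruned, removed = blocked_everywhere)
}

#' Classify dead-end metabolites
#'
#' Structural classification with reversibility expansion: a reversible
#' reaction counts as both producer and consumer of each participant. A
#' metabolite in producing reactions only is \code{produced-only}, in
#' consuming reactions only \code{consumed-only}, in no reaction
#' \code{disconnected}. Metabolites appearing in exactly one (reversible)
#' reaction are not dead ends but are flagged \code{single-reaction}.
#'
#' @param model a \code{metabolic_model}.
#' @return data.frame (\code{metabolite}, \code{class}) of dead ends, with a
#'   \code{single_reaction} character-vector attribute.
#' @export
classify_dead_ends <- function(model) {
  mets <- model$metabolites$id
  produced <- stats::setNames(logical(length(mets)), mets)
  consumed <- produced
  nrxn <- stats::setNames(integer(length(mets)), mets)
  for (r in model$reactions) {
    rev_fwd <- r$ub > 0; rev_bwd <- r$lb < 0
    for (m in names(r$stoich)) {
      s <- r$stoich[[m]]
      nrxn[m] <- nrxn[m] + 1L
      if ((s > 0 && rev_fwd) || (s < 0 && rev_bwd)) produced[m] <- TRUE
      if ((s < 0 && rev_fwd) || (s > 0 && rev_bwd)) consumed[m] <- TRUE
    }
  }
  cls <- character(0); who <- character(0)
  for (m in mets) {
    k <- if (nrxn[m] == 0L) "disconnected"
    else if (produced[m] && !consumed[m]) "produced-only"
    else if (consumed[m] && !produced[m]) "consumed-only"
    else NA_character_
    if (!is.na(k)) { who <- c(who, m); cls <- c(cls, k) }
  }
  out <- data.frame(metabolite = who, class = cls, stringsAsFactors = FALSE)
  attr(out, "single_reaction") <-
    mets[nrxn == 1L & produced & consumed]
  out
}

#' Parsimony gap-filling from a universal reaction pool
#'
#' Finds a deletion-minimal set of pool reactions whose addition raises the
#' target objective above the growth threshold (0.001 1/h, the growth-call
#' threshold used throughout the screens). For pools of at most
#' \code{exhaustive_limit} reactions the search enumerates subsets by
#' increasing size (lexicographic within a size, so ties resolve to the
#' lexicographically first set); larger pools use greedy forward selection
#' followed by a deletion-minimality prune.
#'
#' @param model a \code{metabolic_model} that fails to grow.
#' @param pool a \code{metabolic_model} whose reactions are candidates;
#'   reaction ids must be disjoint from the model's.
#' @param target objective reaction id (defaults to the model's objective).
#' @param medium optional [medium_spec()].
#' @param threshold growth threshold (1/h).
#' @param exhaustive_limit largest pool size searched exhaustively.
#' @return object of class \code{gapfill_solution}: \code{added} (ordered
#'   reaction ids; empty if the model already grows), \code{objective},
#'   \code{status} (\code{"filled"}, \code{"already-growing"} or
#'   \code{"unfillable"}) and, when unfillable, \code{dead_ends} listing the
#'   closest dead-end metabolites.
#' @export
gapfill <- function(model, pool, target = model$objective, medium = NULL,
                    threshold = 0.001, exhaustive_limit = 12L) {
  if (!is.null(medium)) model <- apply_medium(model, medium)
  overlap <- intersect(names(pool$reactions), names(model$reactions))
  if (length(overlap))
    stop("pool reaction ids overlap the model: ", paste(overlap, collapse = ", "))
  grow <- function(m) {
    sol <- fba(m, target)
    if (sol$status == "optimal") sol$objective_value else 0
  }
  with_rxns <- function(ids) {
    m <- model
    for (rid in ids) {
      r <- pool$reactions[[rid]]
      new_mets <- pool$metabolites[pool$metabolites$id %in%
        setdiff(names(r$stoich), m$metabolites$id), , drop = FALSE]
      r$provenance <- "gapfilled"
      m <- add_reaction(m, r, new_metabolites = new_mets)
    }
    m
  }
  base <- grow(model)
  mk <- function(added, obj, status, dead = NULL)
    structure(list(added = added, objective = obj, status = status,
                   dead_ends = dead), class = "gapfill_solution")
  if (base > threshold) return(mk(character(0), base, "already-growing"))
  ids <- sort(names(pool$reactions))
  if (length(ids) <= exhaustive_limit) {
    for (k in seq_along(ids)) {
      for (sel in utils::combn(ids, k, simplify = FALSE)) {
        obj <- grow(with_rxns(sel))
        if (obj > threshold) return(mk(sel, obj, "filled"))
      }
    }
    return(mk(character(0), base, "unfillable",
              dead = classify_dead_ends(model)))
  }
  ## greedy forward selection with deletion prune
  chosen <- character(0); remaining <- ids
  repeat {
    objs <- vapply(remaining, function(rid) grow(with_rxns(c(chosen, rid))),
                   numeric(1))
    if (max(objs) > threshold) { chosen <- c(chosen, remaining[which.max(objs)]); break }
    # no single addition suffices yet: take the best improver
    best <- remaining[which.max(objs)]
    if (objs[which.max(objs)] <= grow(with_rxns(chosen)) + 1e-12) {
      # no progress possible
      return(mk(character(0), base, "unfillable",
                dead = classify_dead_ends(model)))
    }
    chosen <- c(chosen, best)
    remaining <- setdiff(remaining, best)
    if (length(remaining) == 0L)
      return(mk(character(0), base, "unfillable",
                dead = classify_dead_ends(model)))
  }
  for (rid in rev(chosen)) {
    trial <- setdiff(chosen, rid)
    if (grow(with_rxns(trial)) > threshold) chosen <- trial
  }
  mk(sort(chosen), grow(with_rxns(chosen)), "filled")
}

#' @export
print.gapfill_solution <- function(x, ...) {
  cat("<gapfill_solution> ", x$status, sep = "")
  if (length(x$added))
    cat(": +", paste(x$added, collapse = ", "), sep = "")
  cat(" (objective ", format(x$objective, digits = 6), ")\n", sep = "")
  invisible(x)
}
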