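#' Read or write a model in the community cobra-JSON dialect
#'
#' The JSON layout mirrors the cobra toolbox dialect: top-level
#' \code{metabolites}, \code{reactions}, \code{genes}, \code{compartments};
#' reactions carry a \code{metabolites} coefficient map, numeric bounds, a
#' \code{gene_reaction_rule} string and a \code{subsystem}. Package-specific
#' fields (provenance, pseudo-reaction flag) travel in each reaction's
#' \code{annotation} block, so files written here stay readable by other
#' cobra-JSON consumers.
#'
#' @param path file path.
#' @param format \code{"json"} or \code{"sbml"}; default guesses from the
#'   file extension (.json vs .xml/.sbml).
#' @return [read_model()] returns a validated \code{metabolic_model};
#'   [write_model()] returns \code{path} invisibly.
#' @seealso [read_sbml()], [write_sbml()]
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") read_json_model(path) else read_sbml(path)
}

#' @rdname read_model
#' @param model a \code{metabolic_model}.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  if (format == "json") write_json_model(model, path) else write_sbml(model, path)
}

#' @rdname read_model
#' @export
read_json_model <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed model JSON in '", path,
                                           "': ", conditionMessage(e)))
  for (field in c("metabolites", "reactions"))
    if (is.null(doc[[field]]))
      stop("model JSON '", path, "' lacks required entity list: ", field)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite without id in '", path, "'")
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               charge = if (is.null(m$charge)) NA_real_ else as.numeric(m$charge),
               compartment = if (is.null(m$compartment))
                 sub("^.*_", "", m$id) else m$compartment,
               stringsAsFactors = FALSE)
  }))
  objective <- character()
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction without id in '", path, "'")
    coef <- unlist(r$metabolites)
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0)
      objective <<- c(objective, r$id)
    ann <- r$annotation
    reaction(id = r$id,
             stoich = coef,
             lb = if (is.null(r$lower_bound)) -1000 else r$lower_bound,
             ub = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
             name = if (is.null(r$name)) r$id else r$name,
             subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
             gpr = parse_gpr(r$gene_reaction_rule),
             provenance = if (is.null(ann$provenance)) "native" else ann$provenance,
             pseudo = isTRUE(ann$pseudo))
  })
  genes <- vapply(doc$genes, function(g) g$id, "")
  comps <- if (is.null(doc$compartments))
    c(c = "cytoplasm", p = "periplasm", e = "extracellular space")
  else unlist(doc$compartments)
  metabolic_model(id = if (is.null(doc$id)) tools::file_path_sans_ext(basename(path)) else doc$id,
                  metabolites = mets, reactions = rxns,
                  genes = if (length(genes)) genes else NULL,
                  objective = if (length(objective)) objective[1] else NULL,
                  compartments = comps)
}

#' @rdname read_model
#' @export
write_json_model <- function(model, path) {
  validate_model(model)
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(r$stoich[order(names(r$stoich))]),
                lower_bound = r$lb, upper_bound = r$ub,
                gene_reaction_rule = deparse_gpr(r$gpr),
                subsystem = r$subsystem,
                objective_coefficient =
                  if (!is.null(model$objective) && r$id %in% model$objective) 1 else 0,
                annotation = list(provenance = r$provenance))
    if (r$pseudo) out$annotation$pseudo <- TRUE
    out
  })
  doc <- list(id = model$id,
              compartments = as.list(model$compartments),
              metabolites = mets,
              reactions = unname(rxns),
              genes = lapply(model$genes, function(g) list(id = g, name = g)),
              version = "1")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
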