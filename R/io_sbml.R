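## SBML Level 3 Version 1 + FBC version 2 serialisation, built on xml2.
## Identifier convention: species "M_<id>", reactions "R_<id>", gene
## products "G_<id>". Flux bounds are emitted as shared global parameters
## (FBC-strict style); GPR trees map to fbc:geneProductAssociation nodes.
## Subsystem and provenance ride in an xhtml <notes> body, the same place
## legacy cobra SBML keeps them.

.sbml_core_ns <- "http://www.sbml.org/sbml/level3/version1/core"
.sbml_fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

.sbml_check_ids <- function(ids, what) {
  bad <- ids[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", ids)]
  if (length(bad))
    stop("ids not encodable as SBML SIds (", what, "): ",
         paste(bad, collapse = ", "))
}

#' Write a model as SBML L3V1 with the FBC v2 package
#'
#' @param model a \code{metabolic_model}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  .sbml_check_ids(model$metabolites$id, "metabolites")
  .sbml_check_ids(names(model$reactions), "reactions")
  .sbml_check_ids(model$genes, "genes")
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  L <- character(0)
  add <- function(...) L <<- c(L, paste0(...))
  add('<?xml version="1.0" encoding="UTF-8"?>')
  add('<sbml xmlns="', .sbml_core_ns, '" xmlns:fbc="', .sbml_fbc_ns,
      '" level="3" version="1" fbc:required="false">')
  add('  <model id="', model$id, '" fbc:strict="true">')
  add('    <listOfCompartments>')
  for (k in names(model$compartments))
    add('      <compartment id="', k, '" name="', esc(model$compartments[[k]]),
        '" constant="true"/>')
  add('    </listOfCompartments>')
  add('    <listOfSpecies>')
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    extra <- ""
    if (!is.na(m$charge))
      extra <- paste0(extra, ' fbc:charge="', num(m$charge), '"')
    if (!is.na(m$formula))
      extra <- paste0(extra, ' fbc:chemicalFormula="', m$formula, '"')
    add('      <species id="M_', m$id, '" name="', esc(m$name),
        '" compartment="', m$compartment,
        '" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"',
        extra, '/>')
  }
  add('    </listOfSpecies>')
  ## shared bound parameters
  bounds <- sort(unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub)))))
  pid <- function(v) paste0("fb_", gsub("[^0-9A-Za-z]", "_",
                                        sub("-", "m", num(v))))
  add('    <listOfParameters>')
  for (v in bounds)
    add('      <parameter id="', pid(v), '" value="', num(v),
        '" constant="true" sboTerm="SBO:0000626"/>')
  add('    </listOfParameters>')
  gpr_xml <- function(node, indent) {
    pad <- strrep(" ", indent)
    if (node$kind == "gene")
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="G_', node$gene, '"/>'))
    tag <- if (node$kind == "and") "fbc:and" else "fbc:or"
    c(paste0(pad, "<", tag, ">"),
      unlist(lapply(node$children, gpr_xml, indent = indent + 2)),
      paste0(pad, "</", tag, ">"))
  }
  add('    <listOfReactions>')
  for (r in model$reactions) {
    add('      <reaction id="R_', r$id, '" name="', esc(r$name),
        '" reversible="', if (r$lb < 0) "true" else "false",
        '" fast="false" fbc:lowerFluxBound="', pid(r$lb),
        '" fbc:upperFluxBound="', pid(r$ub), '">')
    add('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
        '<p>SUBSYSTEM: ', esc(r$subsystem), '</p>',
        '<p>PROVENANCE: ', esc(r$provenance), '</p>',
        if (r$pseudo) '<p>PSEUDO: true</p>' else '',
        '</body></notes>')
    sto <- r$stoich[order(names(r$stoich))]   # canonical order
    subs <- sto[sto < 0]; prods <- sto[sto > 0]
    if (length(subs)) {
      add('        <listOfReactants>')
      for (k in names(subs))
        add('          <speciesReference species="M_', k, '" stoichiometry="',
            num(-subs[[k]]), '" constant="true"/>')
      add('        </listOfReactants>')
    }
    if (length(prods)) {
      add('        <listOfProducts>')
      for (k in names(prods))
        add('          <speciesReference species="M_', k, '" stoichiometry="',
            num(prods[[k]]), '" constant="true"/>')
      add('        </listOfProducts>')
    }
    if (!is.null(r$gpr)) {
      add('        <fbc:geneProductAssociation>')
      add(paste(gpr_xml(r$gpr, 10), collapse = "\n"))
      add('        </fbc:geneProductAssociation>')
    }
    add('      </reaction>')
  }
  add('    </listOfReactions>')
  if (!is.null(model$objective)) {
    add('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    add('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    add('        <fbc:listOfFluxObjectives>')
    for (oid in model$objective)
      add('          <fbc:fluxObjective fbc:reaction="R_', oid,
          '" fbc:coefficient="1"/>')
    add('        </fbc:listOfFluxObjectives>')
    add('      </fbc:objective>')
    add('    </fbc:listOfObjectives>')
  }
  if (length(model$genes)) {
    add('    <fbc:listOfGeneProducts>')
    for (g in model$genes)
      add('      <fbc:geneProduct fbc:id="G_', g, '" fbc:label="', g, '"/>')
    add('    </fbc:listOfGeneProducts>')
  }
  add('  </model>')
  add('</sbml>')
  writeLines(L, path)
  invisible(path)
}

#' Read an SBML L3/FBC model
#'
#' Parses species (with fbc charge/formula), shared flux-bound parameters,
#' reactions with reactant/product stoichiometry, gene-product associations
#' and the active FBC objective. The \code{M_}/\code{R_}/\code{G_} prefixes
#' are stripped when present.
#'
#' @param path SBML file path.
#' @return a validated \code{metabolic_model}.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML XML in '", path,
                                           "': ", conditionMessage(e)))
  find <- function(node, what)
    xml2::xml_find_all(node, paste0(".//*[local-name()='", what, "']"))
  attr1 <- function(node, name) {
    a <- xml2::xml_attrs(node)
    hit <- which(names(a) == name | grepl(paste0(":", name, "$"), names(a)))
    if (length(hit)) a[[hit[1]]] else NA_character_
  }
  strip <- function(x, pre) ifelse(startsWith(x, pre), substring(x, nchar(pre) + 1L), x)
  mnode <- find(doc, "model")
  if (length(mnode) == 0L) stop("no <model> element in '", path, "'")
  mnode <- mnode[[1]]
  comp_nodes <- find(mnode, "compartment")
  comps <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
           xml2::xml_attr(comp_nodes, "id"),
           xml2::xml_attr(comp_nodes, "name")),
    xml2::xml_attr(comp_nodes, "id"))
  sp <- find(mnode, "species")
  if (length(sp) == 0L) stop("no species in '", path, "'")
  mets <- do.call(rbind, lapply(sp, function(s) {
    id <- strip(attr1(s, "id"), "M_")
    data.frame(id = id,
               name = { n <- attr1(s, "name"); if (is.na(n)) id else n },
               formula = attr1(s, "chemicalFormula"),
               charge = suppressWarnings(as.numeric(attr1(s, "charge"))),
               compartment = attr1(s, "compartment"),
               stringsAsFactors = FALSE)
  }))
  pars <- find(mnode, "parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(gpr_gene(strip(attr1(node, "geneProduct"), "G_")))
    kids <- xml2::xml_children(node)
    kids <- kids[xml2::xml_name(kids) %in% c("and", "or", "geneProductRef")]
    parts <- lapply(kids, parse_assoc)
    if (nm == "and") return(.gpr_node("and", parts))
    if (nm == "or") return(.gpr_node("or", parts))
    if (length(parts) == 1L) return(parts[[1]])
    stop("unsupported geneProductAssociation node: ", nm)
  }
  note_field <- function(rnode, key) {
    ps <- find(rnode, "p")
    txt <- xml2::xml_text(ps)
    hit <- grep(paste0("^", key, ": "), txt, value = TRUE)
    if (length(hit)) sub(paste0("^", key, ": "), "", hit[1]) else NA_character_
  }
  rx <- find(mnode, "reaction")
  rxns <- lapply(rx, function(r) {
    rid <- strip(attr1(r, "id"), "R_")
    refs <- function(tag, sign) {
      lst <- find(r, tag)
      if (length(lst) == 0L) return(numeric(0))
      sr <- find(lst[[1]], "speciesReference")
      stats::setNames(sign * as.numeric(xml2::xml_attr(sr, "stoichiometry")),
                      strip(xml2::xml_attr(sr, "species"), "M_"))
    }
    sto <- c(refs("listOfReactants", -1), refs("listOfProducts", 1))
    sto <- tapply(sto, names(sto), sum)
    sto <- stats::setNames(as.numeric(sto), names(sto))
    lbid <- attr1(r, "lowerFluxBound"); ubid <- attr1(r, "upperFluxBound")
    assoc_node <- find(r, "geneProductAssociation")
    gpr <- if (length(assoc_node)) parse_assoc({
      kids <- xml2::xml_children(assoc_node[[1]])
      kids[xml2::xml_name(kids) %in% c("and", "or", "geneProductRef")][[1]]
    }) else NULL
    prov <- note_field(r, "PROVENANCE")
    subsys <- note_field(r, "SUBSYSTEM")
    reaction(id = rid,
             stoich = sto,
             lb = if (!is.na(lbid) && lbid %in% names(parval)) parval[[lbid]] else -1000,
             ub = if (!is.na(ubid) && ubid %in% names(parval)) parval[[ubid]] else 1000,
             name = { n <- attr1(r, "name"); if (is.na(n)) rid else n },
             subsystem = if (is.na(subsys)) "" else subsys,
             gpr = gpr,
             provenance = if (is.na(prov)) "native" else prov,
             pseudo = identical(note_field(r, "PSEUDO"), "true"))
  })
  gp <- find(mnode, "geneProduct")
  genes <- strip(xml2::xml_attr(gp, "id"), "G_")
  fobj <- find(mnode, "fluxObjective")
  objective <- if (length(fobj))
    strip(attr1(fobj[[1]], "reaction"), "R_") else NULL
  metabolic_model(id = { i <- attr1(mnode, "id"); if (is.na(i))
                    tools::file_path_sans_ext(basename(path)) else i },
                  metabolites = mets, reactions = rxns,
                  genes = if (length(genes)) genes else NULL,
                  objective = objective, compartments = comps)
}
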