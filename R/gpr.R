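#' Gene-protein-reaction (GPR) boolean trees
#'
#' A GPR association is a boolean expression over gene identifiers stating
#' which gene products must be present for a reaction to be catalysable.
#' Trees are nested lists with a \code{kind} of \code{"gene"}, \code{"and"}
#' or \code{"or"}; \code{NULL} stands for the empty (orphan) association,
#' which is always active.
#'
#' @param gene a single gene identifier.
#' @param ... two or more child nodes for \code{gpr_and}/\code{gpr_or}.
#' @return a GPR tree node.
#' @examples
#' g <- gpr_or(gpr_and(gpr_gene("nifH"), gpr_gene("nifD")), gpr_gene("anfH"))
#' eval_gpr(g, knocked = c("nifH"))
#' @export
gpr_gene <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  structure(list(kind = "gene", gene = gene), class = "gpr")
}

#' @rdname gpr_gene
#' @export
gpr_and <- function(...) .gpr_node("and", list(...))

#' @rdname gpr_gene
#' @export
gpr_or <- function(...) .gpr_node("or", list(...))

.gpr_node <- function(kind, children) {
  children <- children[!vapply(children, is.null, logical(1))]
  if (length(children) < 2L)
    stop("'", kind, "' nodes need at least two children")
  structure(list(kind = kind, children = children), class = "gpr")
}

#' Parse a gene_reaction_rule string into a GPR tree
#'
#' Accepts the cobra-style syntax: gene identifiers combined with
#' case-insensitive \code{and} / \code{or} and parentheses. \code{and} binds
#' tighter than \code{or}. An empty or all-whitespace string gives
#' \code{NULL} (orphan reaction).
#'
#' @param rule character scalar.
#' @return a GPR tree or \code{NULL}.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    left <- parse_and()
    parts <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      parts[[length(parts) + 1L]] <- parse_and()
    }
    if (length(parts) == 1L) parts[[1L]] else .gpr_node("or", parts)
  }
  parse_and <- function() {
    left <- parse_atom()
    parts <- list(left)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      parts[[length(parts) + 1L]] <- parse_atom()
    }
    if (length(parts) == 1L) parts[[1L]] else .gpr_node("and", parts)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR rule ended unexpectedly: ", rule)
    if (t == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || advance() != ")")
        stop("unbalanced parentheses in GPR rule: ", rule)
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("unexpected token '", t, "' in GPR rule: ", rule)
    gpr_gene(advance())
  }
  out <- parse_or()
  if (pos <= length(toks))
    stop("trailing tokens in GPR rule: ", rule)
  out
}

#' Serialise a GPR tree back to a rule string
#' @param gpr a GPR tree or NULL.
#' @return character scalar ("" for NULL).
#' @export
deparse_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  rec <- function(node, parent) {
    if (node$kind == "gene") return(node$gene)
    sep <- if (node$kind == "and") " and " else " or "
    s <- paste(vapply(node$children, rec, "", node$kind), collapse = sep)
    # parenthesise when precedence demands or for clarity under a parent op
    if (!is.na(parent) && parent != node$kind) paste0("(", s, ")") else s
  }
  rec(gpr, NA_character_)
}

#' List the gene identifiers in a GPR tree
#' @param gpr a GPR tree or NULL.
#' @return character vector (unique, in first-appearance order).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character())
  if (gpr$kind == "gene") return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}

#' Evaluate a GPR tree under a gene knock-out set
#'
#' A gene leaf is active iff the gene is not knocked out; \code{and} nodes
#' require all children, \code{or} nodes any child. The empty association
#' (\code{NULL}) is always active: orphan reactions are not silenced by any
#' knock-out.
#'
#' @param gpr GPR tree or NULL.
#' @param knocked character vector of knocked-out gene ids.
#' @return logical scalar.
#' @export
eval_gpr <- function(gpr, knocked = character()) {
  if (is.null(gpr)) return(TRUE)
  switch(gpr$kind,
    gene = !(gpr$gene %in% knocked),
    and  = all(vapply(gpr$children, eval_gpr, logical(1), knocked = knocked)),
    or   = any(vapply(gpr$children, eval_gpr, logical(1), knocked = knocked)),
    stop("invalid GPR node kind: ", gpr$kind))
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", deparse_gpr(x), "\n", sep = "")
  invisible(x)
}

#' Structural equality of two GPR trees
#' @param a,b GPR trees or NULL.
#' @return logical scalar.
#' @export
gpr_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  if (a$kind != b$kind) return(FALSE)
  if (a$kind == "gene") return(a$gene == b$gene)
  if (length(a$children) != length(b$children)) return(FALSE)
  all(mapply(gpr_equal, a$children, b$children))
}
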