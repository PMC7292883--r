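#' Parse a Hill-notation chemical formula
#'
#' Formulas are element symbols (one capital letter optionally followed by a
#' lower-case letter, plus the generic residue symbols X and R used for
#' protein/cofactor moieties) each followed by an optional non-negative
#' count. Repeated elements accumulate.
#'
#' @param formula character scalar, e.g. \code{"C10H12N5O13P3"}. \code{NA}
#'   or \code{""} give an empty count vector.
#' @return named numeric vector of atom counts.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("parse_formula() takes a single formula")
  if (is.na(formula) || !nzchar(formula)) return(stats::setNames(numeric(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula))
    stop("cannot parse chemical formula: '", formula, "'")
  sym <- sub("[0-9]*$", "", toks)
  cnt <- as.numeric(ifelse(grepl("[0-9]$", toks), sub("^[A-Z][a-z]?", "", toks), "1"))
  out <- tapply(cnt, sym, sum)
  stats::setNames(as.numeric(out), names(out))
}

#' Element-count matrix of a model's metabolites
#'
#' @param model a \code{metabolic_model}.
#' @return numeric matrix, elements x metabolites; metabolites whose formula
#'   is missing get an all-NA column.
#' @export
element_matrix <- function(model) {
  mets <- model$metabolites
  counts <- lapply(seq_len(nrow(mets)), function(i) {
    f <- mets$formula[i]
    if (is.na(f)) NULL else parse_formula(f)
  })
  elements <- sort(unique(unlist(lapply(counts, names))))
  E <- matrix(0, length(elements), nrow(mets),
              dimnames = list(elements, mets$id))
  for (i in seq_along(counts)) {
    if (is.null(counts[[i]])) { E[, i] <- NA_real_; next }
    E[names(counts[[i]]), i] <- counts[[i]]
  }
  E
}
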