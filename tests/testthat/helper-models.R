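# Shared fixtures and independent oracles used across the suite.

# TOY3 built in code (the same network ships as inst/extdata/toy3.json):
# EX_A <-> A_e -> A_c -> B_c -> (biomass drain)
toy3_model <- function(uptake = 10) {
  mets <- data.frame(id = c("A_e", "A_c", "B_c"),
                     name = c("A (ext)", "A", "B"),
                     formula = "C", charge = 0,
                     compartment = c("e", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- list(
    reaction("EX_A", c(A_e = -1), lb = -uptake, ub = 1000,
             subsystem = "Exchange"),
    reaction("At", c(A_e = -1, A_c = 1), lb = 0, ub = 1000,
             subsystem = "Transport"),
    reaction("R1", c(A_c = -1, B_c = 1), lb = 0, ub = 1000,
             subsystem = "Core", gpr = gpr_gene("g1")),
    reaction("BIO", c(B_c = -1), lb = 0, ub = 1000,
             subsystem = "Biomass and maintenance functions", pseudo = TRUE))
  metabolic_model("TOY3", mets, rxns, objective = "BIO",
                  compartments = c(c = "cytoplasm", e = "extracellular space"))
}

toy3_path <- function() {
  p <- system.file("extdata", "toy3.json", package = "diazogem")
  if (nzchar(p)) p else file.path("..", "..", "inst", "extdata", "toy3.json")
}

# Random small metabolic-style LP instance generator (S v = 0, box bounds).
random_lp <- function(seed) {
  set.seed(seed)
  m <- sample(2:5, 1); n <- sample(4:9, 1)
  S <- matrix(sample(c(-2, -1, -1, 0, 0, 0, 1, 1, 2), m * n, replace = TRUE),
              m, n)
  lb <- ifelse(runif(n) < 0.4, -round(runif(n, 0, 10), 2), 0)
  ub <- lb + round(runif(n, 0.5, 10), 2)
  cc <- round(runif(n, -2, 2), 2)
  list(S = S, lb = lb, ub = ub, cc = cc)
}

# Independent LP oracle: brute-force vertex enumeration. A vertex of
# {S v = 0, lb <= v <= ub} has at least n - rank(S) variables at a bound;
# enumerate all basic/nonbasic splits and all bound assignments of the
# nonbasics, solve the square system for the basics, keep feasible points.
# Exponential, usable only for n <= ~10; entirely independent of the
# simplex implementation it cross-checks.
lp_enum_oracle <- function(cc, S, lb, ub, sense = "max", tol = 1e-7) {
  n <- ncol(S); m <- nrow(S)
  r <- qr(S)$rank
  best <- NA_real_; feas <- FALSE
  basis_sets <- if (r == 0) list(integer(0)) else
    utils::combn(n, r, simplify = FALSE)
  # work with an independent row basis of S (feasibility is still checked
  # against the full S below)
  rows <- if (r == 0) integer(0) else qr(t(S))$pivot[seq_len(r)]
  Sr <- S[rows, , drop = FALSE]
  for (bset in basis_sets) {
    B <- Sr[, bset, drop = FALSE]
    if (length(bset) && abs(det(B)) < 1e-10) next
    nb <- setdiff(seq_len(n), bset)
    grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(nb)))
    if (nrow(grid) == 0) grid <- data.frame(row.names = 1)
    for (g in seq_len(nrow(grid))) {
      x <- numeric(n)
      if (length(nb))
        x[nb] <- ifelse(unlist(grid[g, ]), ub[nb], lb[nb])
      if (length(bset)) {
        rhs <- -Sr[, nb, drop = FALSE] %*% x[nb]
        xb <- tryCatch(solve(B, rhs), error = function(e) NULL)
        if (is.null(xb)) next
        x[bset] <- xb
      }
      if (any(x < lb - tol) || any(x > ub + tol)) next
      if (max(abs(S %*% x)) > tol) next
      feas <- TRUE
      v <- sum(cc * x)
      if (is.na(best) || (sense == "max" && v > best) ||
          (sense == "min" && v < best)) best <- v
    }
  }
  list(feasible = feas, obj = best)
}

# Brute-force per-atom tally of a reaction's element balance, independent
# of the matrix-product route in element_balance().
atom_tally <- function(model, rid) {
  r <- model$reactions[[rid]]
  out <- list()
  charge <- stats::setNames(model$metabolites$charge, model$metabolites$id)
  for (met in names(r$stoich)) {
    f <- model$metabolites$formula[model$metabolites$id == met]
    counts <- parse_formula(f)
    for (el in names(counts))
      out[[el]] <- (if (is.null(out[[el]])) 0 else out[[el]]) +
        r$stoich[[met]] * counts[[el]]
  }
  out[["charge"]] <- sum(charge[names(r$stoich)] * r$stoich)
  unlist(out)
}
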