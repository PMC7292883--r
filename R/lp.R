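#' Solve a bounded-variable linear program
#'
#' Dense two-phase primal simplex with explicit lower/upper bounds on every
#' variable, the standard form used by flux balance analysis:
#' optimise \code{obj \%*\% x} subject to \code{A \%*\% x == rhs} and
#' \code{lb <= x <= ub}. Nonbasic variables rest at a finite bound; bound
#' flips are handled without basis changes. Bland's rule is switched on after
#' a Dantzig warm-up so the algorithm terminates on degenerate problems
#' (FBA problems are highly degenerate: the right-hand side is all zeros).
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense or sparse constraint matrix (m x n); coerced to dense.
#' @param rhs right-hand side of the equality constraints (length m).
#' @param lb,ub variable bounds; may contain +/-Inf, but at least one bound of
#'   every variable must be finite unless the variable never enters the basis.
#' @param sense "max" or "min".
#' @param tol feasibility/optimality tolerance.
#' @return list with \code{status} ("optimal", "infeasible", "unbounded",
#'   "iteration_limit"), \code{x} (primal solution, length n) and
#'   \code{objval}.
#' @keywords internal
lp_solve <- function(obj, A, rhs, lb, ub, sense = c("max", "min"),
                     tol = 1e-9) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  if (any(is.infinite(lb) & is.infinite(ub)))
    stop("lp_solve requires at least one finite bound per variable; ",
         "cap free fluxes (the FBA layer uses +/-1000)")
  cc <- if (sense == "max") -as.numeric(obj) else as.numeric(obj)

  ## starting point: every structural variable at its nearest finite bound
  x0 <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  resid <- as.numeric(rhs - A %*% x0)
  sgn <- ifelse(resid >= 0, 1, -1)

  ## extended problem: [A | diag(sgn)] with artificial variables in [0, Inf)
  nt <- n + m
  Ae <- cbind(A, diag(sgn, nrow = m, ncol = m))
  lbe <- c(lb, rep(0, m))
  ube <- c(ub, rep(Inf, m))
  xe <- c(x0, abs(resid))
  basis <- (n + 1L):nt
  at_upper <- is.infinite(lb) & is.finite(ub)   # structural nonbasics at ub
  nb_at_ub <- c(at_upper, rep(FALSE, m))

  run_phase <- function(cost, basis, xe, nb_at_ub, lbe, ube, max_it) {
    bland_after <- 10L * (m + nt)
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_it)
        return(list(status = "iteration_limit", basis = basis, xe = xe,
                    nb_at_ub = nb_at_ub))
      B <- Ae[, basis, drop = FALSE]
      ok <- TRUE
      y <- tryCatch(solve(t(B), cost[basis]), error = function(e) {ok <<- FALSE; NULL})
      if (!ok)
        return(list(status = "singular", basis = basis, xe = xe,
                    nb_at_ub = nb_at_ub))
      d <- cost - as.numeric(crossprod(Ae, y))
      nonbasic <- setdiff(seq_len(nt), basis)
      # candidates: at lb wants d<0 to increase; at ub wants d>0 to decrease
      cand <- nonbasic[(!nb_at_ub[nonbasic] & d[nonbasic] < -tol) |
                       ( nb_at_ub[nonbasic] & d[nonbasic] >  tol)]
      if (length(cand) == 0L)
        return(list(status = "optimal", basis = basis, xe = xe,
                    nb_at_ub = nb_at_ub))
      j <- if (it > bland_after) min(cand) else cand[which.max(abs(d[cand]))]
      up <- !nb_at_ub[j]                 # TRUE: entering increases from lb
      w <- solve(B, Ae[, j])
      # x_B moves by -w*t (entering up) or +w*t (entering down), t >= 0
      dirB <- if (up) -w else w
      tmax <- ube[j] - lbe[j]            # bound-flip distance (may be Inf)
      leave <- 0L                        # 0 => bound flip
      for (k in seq_len(m)) {
        if (dirB[k] < -tol) {
          lim <- (xe[basis[k]] - lbe[basis[k]]) / (-dirB[k])
        } else if (dirB[k] > tol) {
          lim <- (ube[basis[k]] - xe[basis[k]]) / dirB[k]
        } else next
        if (lim < tmax - tol ||
            (lim < tmax + tol && leave != 0L && basis[k] < basis[leave])) {
          tmax <- max(lim, 0); leave <- k
        }
      }
      if (!is.finite(tmax))
        return(list(status = "unbounded", basis = basis, xe = xe,
                    nb_at_ub = nb_at_ub))
      # apply step
      xe[basis] <- xe[basis] + dirB * tmax
      xe[j] <- if (up) lbe[j] + tmax else ube[j] - tmax
      if (leave == 0L) {                 # bound flip, basis unchanged
        nb_at_ub[j] <- !nb_at_ub[j]
      } else {
        lv <- basis[leave]
        # leaving variable parks at the bound it ran into
        nb_at_ub[lv] <- dirB[leave] > 0
        xe[lv] <- if (nb_at_ub[lv]) ube[lv] else lbe[lv]
        basis[leave] <- j
      }
      # refresh basic values from scratch to kill drift
      nonbasic <- setdiff(seq_len(nt), basis)
      B <- Ae[, basis, drop = FALSE]
      bb <- rhs - as.numeric(Ae[, nonbasic, drop = FALSE] %*% xe[nonbasic])
      xb <- tryCatch(solve(B, bb), error = function(e) NULL)
      if (!is.null(xb)) xe[basis] <- xb
    }
  }

  max_it <- 200L * (m + nt) + 200L
  ## phase 1: minimise the artificial mass
  p1 <- run_phase(c(rep(0, n), rep(1, m)), basis, xe, nb_at_ub, lbe, ube, max_it)
  if (p1$status %in% c("iteration_limit", "singular"))
    return(list(status = "iteration_limit", x = NULL, objval = NA_real_))
  art_mass <- sum(p1$xe[(n + 1L):nt])
  if (p1$status != "optimal" || art_mass > 1e-7)
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  ## phase 2: lock artificials at zero, optimise the real objective
  ube2 <- ube; ube2[(n + 1L):nt] <- 0
  xe2 <- p1$xe; xe2[(n + 1L):nt] <- 0
  p2 <- run_phase(c(cc, rep(0, m)), p1$basis, xe2, p1$nb_at_ub, lbe, ube2, max_it)
  if (p2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  if (p2$status != "optimal")
    return(list(status = "iteration_limit", x = NULL, objval = NA_real_))
  x <- p2$xe[seq_len(n)]
  obj_out <- sum(obj * x)
  list(status = "optimal", x = x, objval = obj_out)
}
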