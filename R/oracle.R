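# Brute-force LP oracle: exhaustive vertex enumeration.
#
# Independent of the simplex backend by construction: it enumerates
# active-constraint subsets and solves small linear systems, so its optima
# derive from linear algebra alone. Intended for cross-checking the solver
# on small problems (toy networks, random LPs), never for production use.

#' Solve a flux problem by vertex enumeration
#'
#' Enumerates all basic solutions of the polyhedron `{S v = 0, fixed
#' exchanges at their values, finite bounds}` by activating subsets of the
#' bound constraints, and returns the best feasible vertex. Assumes the
#' optimum is attained at a vertex (bounded problem, pointed feasible
#' region) which holds for the toy networks it is used on.
#'
#' @param problem A `flux_problem`.
#' @param max_dims Refuse when more than `max_dims` free dimensions remain
#'   after the equalities (the enumeration is exponential).
#' @param max_bases Hard cap on enumerated subsets.
#' @param tol Feasibility/rank tolerance.
#' @return A `flux_solution` (status `"OPTIMAL"` or `"INFEASIBLE"`).
#' @export
brute_force_lp <- function(problem, max_dims = 8, max_bases = 200000,
                           tol = 1e-8) {
  stopifnot(inherits(problem, "flux_problem"))
  n <- length(problem$reaction_ids)
  S <- as.matrix(problem$S)
  lb <- problem$lb; ub <- problem$ub
  fixed <- which(is.finite(lb) & is.finite(ub) & abs(ub - lb) <= tol)
  E <- S
  e_rhs <- rep(0, nrow(S))
  for (j in fixed) {
    row <- numeric(n); row[j] <- 1
    E <- rbind(E, row)
    e_rhs <- c(e_rhs, lb[j])
  }
  # candidate active bounds: (variable index, bound value)
  cand <- list()
  for (j in setdiff(seq_len(n), fixed)) {
    if (is.finite(lb[j])) cand[[length(cand) + 1L]] <- c(j, lb[j])
    if (is.finite(ub[j])) cand[[length(cand) + 1L]] <- c(j, ub[j])
  }
  qE <- qr(E)
  r <- qE$rank
  k <- n - r
  if (k > max_dims) {
    stop(sprintf("brute_force_lp refused: %d free dimensions exceed max_dims = %d",
                 k, max_dims))
  }
  feas_ok <- function(v) {
    lo <- is.finite(lb); hi <- is.finite(ub)
    all(v[lo] >= lb[lo] - tol * (1 + abs(lb[lo]))) &&
      all(v[hi] <= ub[hi] + tol * (1 + abs(ub[hi]))) &&
      max(abs(E %*% v - e_rhs)) <= tol * max(1, max(abs(e_rhs)))
  }
  best <- NULL; best_obj <- -Inf
  consider <- function(v) {
    if (!feas_ok(v)) return(invisible(NULL))
    o <- sum(problem$obj * v)
    if (o > best_obj + tol) { best_obj <<- o; best <<- v }
    invisible(NULL)
  }
  if (k == 0L) {
    v <- qr.coef(qE, e_rhs)
    v[is.na(v)] <- 0
    if (max(abs(E %*% v - e_rhs)) <= tol * max(1, max(abs(e_rhs)))) consider(v)
  } else {
    if (length(cand) < k) {
      # not enough bounds to pin a vertex: feasible set has free directions
      stop("brute_force_lp: feasible region is not pointed (too few bounds)")
    }
    subsets <- utils::combn(length(cand), k)
    if (ncol(subsets) > max_bases) {
      stop(sprintf("brute_force_lp refused: %d candidate bases exceed max_bases",
                   ncol(subsets)))
    }
    for (ci in seq_len(ncol(subsets))) {
      sel <- cand[subsets[, ci]]
      vars <- vapply(sel, `[`, numeric(1), 1)
      if (anyDuplicated(vars)) next
      Ab <- E
      rhs <- e_rhs
      for (s in sel) {
        row <- numeric(n); row[s[1]] <- 1
        Ab <- rbind(Ab, row)
        rhs <- c(rhs, s[2])
      }
      qa <- qr(Ab)
      if (qa$rank < n) next
      v <- qr.coef(qa, rhs)
      if (anyNA(v)) next
      if (max(abs(Ab %*% v - rhs)) > tol * max(1, max(abs(rhs)))) next
      consider(v)
    }
  }
  if (is.null(best)) {
    return(structure(list(status = "INFEASIBLE", v = NULL,
                          objective_value = NA_real_),
                     class = "flux_solution"))
  }
  structure(list(status = "OPTIMAL",
                 v = stats::setNames(best, problem$reaction_ids),
                 objective_value = best_obj),
            class = "flux_solution")
}
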