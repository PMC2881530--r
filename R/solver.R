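# Dense two-phase primal simplex with Bland's rule.
#
# Solves  max/min c'x  s.t.  A x = b,  lb <= x <= ub  (entries of lb/ub may
# be -Inf/Inf). This is the LP backend for flux balance problems; Bland's
# rule guarantees termination on the highly degenerate bases that
# steady-state flux problems produce. Correctness is cross-checked in the
# test suite against closed-form optima and an independent
# vertex-enumeration oracle ([brute_force_lp()]).

#' Solve a bounded linear program
#'
#' @param obj Objective coefficient vector (length n).
#' @param A Constraint matrix (m x n), dense or sparse; constraints are
#'   equalities `A x = b`.
#' @param b Right-hand side (length m).
#' @param lb,ub Variable bounds; `-Inf`/`Inf` allowed. Defaults: `0` and
#'   `Inf`.
#' @param sense `"max"` or `"min"`.
#' @param tol Pivot/feasibility tolerance.
#' @param maxit Iteration cap per phase; exceeded caps yield status
#'   `"NUMERICAL"`.
#' @return List with `status` (`"OPTIMAL"`, `"INFEASIBLE"`, `"UNBOUNDED"`,
#'   `"NUMERICAL"`), `x` (primal solution, `NULL` unless optimal) and
#'   `objective`.
#' @export
solve_lp <- function(obj, A, b, lb = rep(0, length(obj)),
                     ub = rep(Inf, length(obj)),
                     sense = c("max", "min"), tol = 1e-9, maxit = NULL) {
  sense <- match.arg(sense)
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "INFEASIBLE", x = NULL, objective = NA_real_))
  }
  cc <- if (sense == "max") -as.numeric(obj) else as.numeric(obj)

  # --- transform to standard form: min c'y, Ay = b, y >= 0 ----------------
  # map: for each original var, record how to recover x from y
  cols <- list()   # one entry per standard-form column: list(var, sign, shift)
  Astd <- matrix(0, m, 0)
  cstd <- numeric(0)
  bstd <- as.numeric(b)
  ubrows <- list() # finite upper bounds -> extra rows (y_j + s = ub')
  for (j in seq_len(n)) {
    aj <- A[, j, drop = TRUE]
    if (is.finite(lb[j]) && is.finite(ub[j]) && abs(ub[j] - lb[j]) <= tol) {
      # fixed variable: substitute out
      bstd <- bstd - aj * lb[j]
      cols[[length(cols) + 1L]] <- list(var = j, fixed = lb[j])
      next
    }
    if (is.finite(lb[j])) {
      # x = lb + y, y >= 0
      bstd <- bstd - aj * lb[j]
      Astd <- cbind(Astd, aj)
      cstd <- c(cstd, cc[j])
      cols[[length(cols) + 1L]] <- list(var = j, sign = 1, shift = lb[j],
                                        col = ncol(Astd))
      if (is.finite(ub[j])) {
        ubrows[[length(ubrows) + 1L]] <- list(col = ncol(Astd),
                                              cap = ub[j] - lb[j])
      }
    } else if (is.finite(ub[j])) {
      # x = ub - y, y >= 0
      bstd <- bstd - aj * ub[j]
      Astd <- cbind(Astd, -aj)
      cstd <- c(cstd, -cc[j])
      cols[[length(cols) + 1L]] <- list(var = j, sign = -1, shift = ub[j],
                                        col = ncol(Astd))
    } else {
      # free: x = y+ - y-
      Astd <- cbind(Astd, aj, -aj)
      cstd <- c(cstd, cc[j], -cc[j])
      cols[[length(cols) + 1L]] <- list(var = j, split = c(ncol(Astd) - 1L,
                                                           ncol(Astd)))
    }
  }
  # upper-bound rows
  for (ubr in ubrows) {
    slack_col <- ncol(Astd) + 1L
    Astd <- cbind(Astd, 0)
    Astd <- rbind(Astd, 0)
    Astd[nrow(Astd), ubr$col] <- 1
    Astd[nrow(Astd), slack_col] <- 1
    cstd <- c(cstd, 0)
    bstd <- c(bstd, ubr$cap)
  }
  nstd <- ncol(Astd)
  mstd <- nrow(Astd)
  if (is.null(maxit)) maxit <- max(2000L, 60L * (nstd + mstd))
  if (nstd == 0L) {
    # all variables fixed: feasible iff residual zero
    xfix <- numeric(n)
    for (cl in cols) if (!is.null(cl$fixed)) xfix[cl$var] <- cl$fixed
    feas <- all(abs(bstd) <= max(tol, 1e-7))
    return(list(status = if (feas) "OPTIMAL" else "INFEASIBLE",
                x = if (feas) xfix else NULL,
                objective = if (feas) sum(obj * xfix) else NA_real_))
  }
  neg <- bstd < 0
  Astd[neg, ] <- -Astd[neg, , drop = FALSE]
  bstd[neg] <- -bstd[neg]

  # --- phase 1 -------------------------------------------------------------
  T1 <- cbind(Astd, diag(mstd))
  cost1 <- c(rep(0, nstd), rep(1, mstd))
  basis <- nstd + seq_len(mstd)
  r1 <- simplex_iterate(T1, bstd, cost1, basis, tol, maxit)
  if (r1$status != "OPTIMAL") {
    return(list(status = "NUMERICAL", x = NULL, objective = NA_real_))
  }
  phase1_obj <- sum(cost1[r1$basis] * r1$b)
  if (phase1_obj > 1e-7 * max(1, max(abs(bstd)))) {
    return(list(status = "INFEASIBLE", x = NULL, objective = NA_real_))
  }
  Tn <- r1$A; bn <- r1$b; basis <- r1$basis
  # drive artificials out of the basis or drop redundant rows
  keep_rows <- rep(TRUE, mstd)
  for (i in seq_len(mstd)) {
    if (basis[i] > nstd) {
      piv <- which(abs(Tn[i, seq_len(nstd)]) > tol)
      piv <- setdiff(piv, basis)
      if (length(piv) > 0L) {
        j <- piv[1]
        fac <- Tn[i, j]
        Tn[i, ] <- Tn[i, ] / fac; bn[i] <- bn[i] / fac
        for (k in seq_len(mstd)) {
          if (k != i && abs(Tn[k, j]) > 0) {
            bn[k] <- bn[k] - Tn[k, j] * bn[i]
            Tn[k, ] <- Tn[k, ] - Tn[k, j] * Tn[i, ]
          }
        }
        basis[i] <- j
      } else {
        keep_rows[i] <- FALSE  # redundant constraint
      }
    }
  }
  Tn <- Tn[keep_rows, seq_len(nstd), drop = FALSE]
  bn <- bn[keep_rows]
  basis <- basis[keep_rows]

  # --- phase 2 -------------------------------------------------------------
  r2 <- simplex_iterate(Tn, bn, cstd, basis, tol, maxit)
  if (r2$status == "UNBOUNDED") {
    return(list(status = "UNBOUNDED", x = NULL,
                objective = if (sense == "max") Inf else -Inf))
  }
  if (r2$status != "OPTIMAL") {
    return(list(status = "NUMERICAL", x = NULL, objective = NA_real_))
  }
  y <- numeric(nstd)
  y[r2$basis] <- r2$b
  x <- numeric(n)
  for (cl in cols) {
    if (!is.null(cl$fixed)) x[cl$var] <- cl$fixed
    else if (!is.null(cl$split)) x[cl$var] <- y[cl$split[1]] - y[cl$split[2]]
    else x[cl$var] <- cl$shift + cl$sign * y[cl$col]
  }
  list(status = "OPTIMAL", x = x, objective = sum(obj * x))
}

# Full-tableau simplex iterations with Bland's rule.
# A must be in canonical form wrt basis (A[, basis] = I), b >= 0.
simplex_iterate <- function(A, b, cost, basis, tol, maxit) {
  m <- nrow(A)
  for (it in seq_len(maxit)) {
    red <- cost - as.numeric(crossprod(cost[basis], A))
    red[basis] <- 0
    entering <- which(red < -tol)
    if (length(entering) == 0L) {
      return(list(status = "OPTIMAL", A = A, b = b, basis = basis))
    }
    j <- min(entering)                       # Bland
    col <- A[, j]
    pos <- which(col > tol)
    if (length(pos) == 0L) {
      return(list(status = "UNBOUNDED", A = A, b = b, basis = basis))
    }
    ratios <- b[pos] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol * (1 + abs(rmin))]
    i <- cand[which.min(basis[cand])]        # Bland
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    fac <- A[, j]
    rows <- which(abs(fac) > 0 & seq_len(m) != i)
    if (length(rows) > 0L) {
      b[rows] <- b[rows] - fac[rows] * b[i]
      A[rows, ] <- A[rows, , drop = FALSE] - outer(fac[rows], A[i, ])
    }
    basis[i] <- j
  }
  list(status = "MAXIT", A = A, b = b, basis = basis)
}
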