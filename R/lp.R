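#' Solve a bounded-variable linear program
#'
#' Maximises `c'v` subject to `A v = b` and `lb <= v <= ub`. This is the
#' workhorse behind [solve_fba()]; it is a dense two-phase primal simplex
#' with explicit upper bounds handled through slack rows and Bland's rule
#' for anti-cycling, sized for desk-scale problems (tens to a few hundred
#' variables). All bounds must be finite.
#'
#' @param obj numeric objective coefficients (maximised).
#' @param A constraint matrix (one row per equality).
#' @param b equality right-hand side.
#' @param lb,ub lower/upper variable bounds, finite, `lb <= ub`.
#' @param tol pivot / feasibility tolerance.
#' @param max_iter simplex iteration cap.
#' @return list with `status` ("optimal", "infeasible", "unbounded" or
#'   "iteration_limit"), `x` (the solution in the original variables, `NULL`
#'   unless optimal) and `value` (objective at `x`).
#' @keywords internal
lp_solve_bounded <- function(obj, A, b, lb, ub, tol = 1e-9, max_iter = 10000L) {
  n <- length(obj)
  A <- as.matrix(A)
  stopifnot(ncol(A) == n, nrow(A) == length(b),
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    ft_abort("lp_solve_bounded requires finite bounds", "state_error")
  if (any(lb > ub + tol))
    ft_abort("lower bound exceeds upper bound", "state_error")

  if (n == 0L) {
    feasible <- !length(b) || max(abs(b)) <= tol
    return(list(status = if (feasible) "optimal" else "infeasible",
                x = numeric(0), value = 0))
  }

  # Shift to x = v - lb >= 0:  A x = b - A lb,  x <= u = ub - lb.
  u <- ub - lb
  rhs_eq <- as.vector(b - A %*% lb)
  m <- nrow(A)

  # Columns x_i with u_i == 0 are fixed at zero; drop them from the search
  # (knockouts and lb==ub pins produce many of these).
  fixed <- u <= tol
  keep <- which(!fixed)
  rhs_eq <- rhs_eq  # fixed columns contribute 0
  A2 <- A[, keep, drop = FALSE]
  u2 <- u[keep]
  c2 <- obj[keep]
  nk <- length(keep)

  if (nk == 0L) {
    feasible <- !length(rhs_eq) || max(abs(rhs_eq)) <= max(tol, 1e-7)
    x <- lb
    return(list(status = if (feasible) "optimal" else "infeasible",
                x = if (feasible) x else NULL,
                value = if (feasible) sum(obj * x) else NA_real_))
  }

  # Standard form: rows = m equality rows + nk bound rows (x + s = u).
  # Variables: x (nk), s (nk), artificials for equality rows (m).
  sgn <- ifelse(rhs_eq < 0, -1, 1)
  Aeq <- A2 * sgn           # row-scale so rhs >= 0
  beq <- rhs_eq * sgn

  n_tot <- nk + nk + m
  M <- matrix(0, nrow = m + nk, ncol = n_tot)
  M[seq_len(m), seq_len(nk)] <- Aeq
  if (m > 0L) M[cbind(seq_len(m), 2L * nk + seq_len(m))] <- 1
  M[m + seq_len(nk), seq_len(nk)] <- diag(1, nk)
  M[cbind(m + seq_len(nk), nk + seq_len(nk))] <- 1
  rhs <- c(beq, u2)
  basis <- c(if (m > 0L) 2L * nk + seq_len(m), nk + seq_len(nk))

  Tm <- cbind(M, rhs)
  art_cols <- if (m > 0L) 2L * nk + seq_len(m) else integer(0)

  pivot <- function(Tm, i, j) {
    piv <- Tm[i, ] / Tm[i, j]
    Tm <- Tm - outer(Tm[, j], piv)
    Tm[i, ] <- piv
    Tm
  }

  run_phase <- function(Tm, basis, cost, allowed, max_iter) {
    rhs_col <- ncol(Tm)
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter)
        return(list(status = "iteration_limit", Tm = Tm, basis = basis))
      cB <- cost[basis]
      red <- cost - as.vector(cB %*% Tm[, -rhs_col, drop = FALSE])
      cand <- allowed[red[allowed] < -tol]
      if (!length(cand))
        return(list(status = "optimal", Tm = Tm, basis = basis))
      j <- min(cand)                              # Bland: lowest index enters
      col <- Tm[, j][seq_len(nrow(Tm))]
      pos <- which(col > tol)
      if (!length(pos))
        return(list(status = "unbounded", Tm = Tm, basis = basis))
      ratios <- Tm[pos, rhs_col] / col[pos]
      rmin <- min(ratios)
      ties <- pos[ratios <= rmin + tol]
      i <- ties[which.min(basis[ties])]           # Bland: lowest basic leaves
      Tm <- pivot(Tm, i, j)
      basis[i] <- j
    }
  }

  # Phase 1: drive artificials out.
  if (m > 0L) {
    cost1 <- c(rep(0, 2L * nk), rep(1, m))
    ph1 <- run_phase(Tm, basis, cost1, seq_len(n_tot), max_iter)
    if (ph1$status != "optimal")
      return(list(status = if (ph1$status == "unbounded") "infeasible" else ph1$status,
                  x = NULL, value = NA_real_))
    Tm <- ph1$Tm; basis <- ph1$basis
    ph1_val <- sum(cost1[basis] * Tm[, ncol(Tm)])
    if (ph1_val > 1e-7)
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    # pivot lingering zero-level artificials out where possible
    for (r in which(basis %in% art_cols)) {
      row <- Tm[r, seq_len(2L * nk)]
      j <- which(abs(row) > tol)
      if (length(j)) {
        Tm <- pivot(Tm, r, j[1L])
        basis[r] <- j[1L]
      }
      # else: redundant equality row; harmless to leave (stays at zero level)
    }
  }

  # Phase 2: maximise c2'x  ==  minimise -c2'x, artificials barred.
  cost2 <- c(-c2, rep(0, nk), rep(1e30, m))
  ph2 <- run_phase(Tm, basis, cost2, seq_len(2L * nk), max_iter)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  if (ph2$status == "iteration_limit")
    return(list(status = "iteration_limit", x = NULL, value = NA_real_))
  Tm <- ph2$Tm; basis <- ph2$basis

  xfull <- numeric(n_tot)
  xfull[basis] <- Tm[, ncol(Tm)]
  xk <- xfull[seq_len(nk)]
  x <- numeric(n)
  x[keep] <- xk
  v <- x + lb
  list(status = "optimal", x = v, value = sum(obj * v))
}
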