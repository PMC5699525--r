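# Linear-programming backend.
#
# Flux balance analysis only ever needs one LP shape:
#
#     maximize  c'x   subject to   A x = b,   lb <= x <= ub
#
# exposed here as lp_solve(), the package's minimal solver contract: any
# routine that can build that problem, solve it and report primal values
# could stand behind it. The default backend is a dense two-phase
# bounded-variable primal simplex with Bland's anti-cycling rule, which is
# ample for the problem sizes this package targets.

#' Solve a box-constrained linear program
#'
#' Maximizes (or minimizes) `t(c) %*% x` subject to \code{A x = b} and
#' \code{lb <= x <= ub}. This is the solver contract used by all flux
#' balance computations in the package.
#'
#' Non-finite bounds are capped at \code{+/-big}; a solution pressing
#' against such an artificial cap is reported as \code{"unbounded"}.
#'
#' @param obj numeric objective coefficients, length n.
#' @param A dense constraint matrix, m x n (rank deficiency is allowed).
#' @param b right-hand side, length m.
#' @param lb,ub variable bounds, length n. May contain \code{-Inf}/\code{Inf}.
#' @param maximize logical; minimize when \code{FALSE}.
#' @param feas_tol feasibility tolerance used in pivoting and in the
#'   phase-1 feasibility decision.
#' @param big cap substituted for non-finite bounds.
#'
#' @return A list with elements \code{status} (optimal, infeasible or
#'   unbounded), \code{x} (primal values, \code{NULL} unless optimal) and
#'   \code{value} (objective value).
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     feas_tol = 1e-9, big = 1e6) {
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + feas_tol)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  capped <- !is.finite(lb) | !is.finite(ub)
  lb2 <- pmax(lb, -big)
  ub2 <- pmin(ub, big)
  cvec <- if (maximize) obj else -obj

  res <- .simplex_bounded(cvec, A, b, lb2, ub2, feas_tol)
  if (res$status == "optimal") {
    # a capped variable sitting at its artificial bound means the true
    # problem is unbounded in that direction (or degenerate there)
    at_cap <- capped & (abs(res$x - big) < 1e-3 * big | abs(res$x + big) < 1e-3 * big)
    hit <- at_cap & (!is.finite(ub) & res$x > 0 | !is.finite(lb) & res$x < 0)
    if (any(hit)) {
      return(list(status = "unbounded", x = NULL, value = NA_real_))
    }
    val <- sum(obj * res$x)
    return(list(status = "optimal", x = res$x, value = val))
  }
  list(status = res$status, x = NULL, value = NA_real_)
}

# Two-phase bounded-variable primal simplex (dense, Bland's rule).
# Returns list(status, x) where x covers the structural variables.
.simplex_bounded <- function(cvec, A, b, lb, ub, tol) {
  m <- nrow(A)
  n <- ncol(A)

  # start: structural variables nonbasic at the bound nearer zero
  x <- ifelse(abs(lb) <= abs(ub), lb, ub)
  at_upper <- abs(lb) > abs(ub)
  r <- b - as.vector(A %*% x)

  # artificial variables absorb the residual: column s_i * e_i, value |r_i|
  s <- ifelse(r >= 0, 1, -1)
  Aall <- cbind(A, diag(s, nrow = m))
  lball <- c(lb, rep(0, m))
  uball <- c(ub, rep(Inf, m))
  ntot <- n + m

  xall <- c(x, abs(r))
  at_up <- c(at_upper, rep(FALSE, m))
  basis <- (n + 1L):ntot
  is_basic <- rep(FALSE, ntot)
  is_basic[basis] <- TRUE

  run_phase <- function(cost, basis, is_basic, xall, at_up, uball, max_iter) {
    for (iter in seq_len(max_iter)) {
      Bmat <- Aall[, basis, drop = FALSE]
      y <- tryCatch(solve(t(Bmat), cost[basis]),
                    error = function(e) NULL)
      if (is.null(y)) return(list(status = "singular"))
      # reduced costs of nonbasic variables
      nonbasic <- which(!is_basic)
      d <- cost[nonbasic] - as.vector(y %*% Aall[, nonbasic, drop = FALSE])
      enter_lo <- nonbasic[d > tol & !at_up[nonbasic]]
      enter_hi <- nonbasic[d < -tol & at_up[nonbasic]]
      cand <- sort(c(enter_lo, enter_hi))  # Bland: smallest index
      if (length(cand) == 0L) {
        return(list(status = "optimal", basis = basis, is_basic = is_basic,
                    xall = xall, at_up = at_up))
      }
      e <- cand[1L]
      dir <- if (at_up[e]) -1 else 1  # entering moves off its bound
      w <- tryCatch(solve(Bmat, Aall[, e]), error = function(e) NULL)
      if (is.null(w)) return(list(status = "singular"))
      # basic variables move by -dir * w * t as entering moves by dir * t
      step <- Inf
      leave <- 0L        # 0: bound flip of entering variable
      leave_to_up <- FALSE
      for (k in seq_len(m)) {
        wk <- dir * w[k]
        if (wk > tol) {         # basic k decreases toward its lower bound
          tk <- (xall[basis[k]] - lball[basis[k]]) / wk
          if (tk < step - tol || (tk < step + tol && (leave == 0L || basis[k] < basis[leave]))) {
            step <- max(tk, 0); leave <- k; leave_to_up <- FALSE
          }
        } else if (wk < -tol) { # basic k increases toward its upper bound
          if (is.finite(uball[basis[k]])) {
            tk <- (uball[basis[k]] - xall[basis[k]]) / (-wk)
            if (tk < step - tol || (tk < step + tol && (leave == 0L || basis[k] < basis[leave]))) {
              step <- max(tk, 0); leave <- k; leave_to_up <- TRUE
            }
          }
        }
      }
      range_e <- uball[e] - lball[e]
      if (is.finite(range_e) && range_e < step) {
        step <- range_e
        leave <- 0L
      }
      if (!is.finite(step)) return(list(status = "unbounded"))
      # update primal values
      xall[e] <- xall[e] + dir * step
      xall[basis] <- xall[basis] - dir * step * w
      if (leave == 0L) {
        at_up[e] <- !at_up[e]   # bound flip, basis unchanged
      } else {
        lv <- basis[leave]
        xall[lv] <- if (leave_to_up) uball[lv] else lball[lv]
        at_up[lv] <- leave_to_up
        is_basic[lv] <- FALSE
        basis[leave] <- e
        is_basic[e] <- TRUE
        at_up[e] <- FALSE
      }
    }
    list(status = "maxiter")
  }

  max_iter <- 200L + 50L * ntot

  # phase 1: minimize the artificial total
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(c1, basis, is_basic, xall, at_up, uball, max_iter)
  if (p1$status != "optimal") {
    return(list(status = if (identical(p1$status, "unbounded")) "infeasible" else "error",
                x = NULL))
  }
  art_total <- sum(p1$xall[(n + 1L):ntot])
  if (art_total > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible", x = NULL))
  }

  # phase 2: pin artificials at zero and optimize the true objective
  uball[(n + 1L):ntot] <- 0
  p1$xall[(n + 1L):ntot] <- pmin(p1$xall[(n + 1L):ntot], 0)
  c2 <- c(cvec, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$is_basic, p1$xall, p1$at_up, uball, max_iter)
  if (p2$status != "optimal") {
    return(list(status = if (identical(p2$status, "unbounded")) "unbounded" else "error",
                x = NULL))
  }
  list(status = "optimal", x = p2$xall[seq_len(n)])
}
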