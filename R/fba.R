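# Flux balance analysis over the lp_solve() contract.
#
# All solves share one problem shape: optimize the flux of a single reaction
# subject to steady state (S v = 0) and the model's flux bounds. Variants
# differ only in which bounds are clamped beforehand (fixed fluxes, closed
# demands, the lexicographic second stage) or in the objective (the
# parsimonious flux-split LP).

.flux_state <- function(fluxes, objective_id, objective_value, status) {
  structure(list(fluxes = fluxes, objective_id = objective_id,
                 objective_value = objective_value, status = status),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("FBA solution (", x$status, ")", sep = "")
  if (x$status == "optimal") {
    cat(": ", x$objective_id, " = ", format(x$objective_value), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Solve a flux balance analysis problem
#'
#' Maximizes (or minimizes) the flux through one reaction subject to
#' steady-state mass balance `S v = 0` and the model's flux bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction whose flux is optimized.
#' @param direction `"max"` or `"min"`.
#' @return A `flux_state`: named flux vector, objective id and value, and a
#'   solver status of `"optimal"`, `"infeasible"` or `"unbounded"` (fluxes
#'   are `NULL` unless optimal).
#' @export
solve_fba <- function(model, objective_id, direction = c("max", "min")) {
  direction <- match.arg(direction)
  i <- match(objective_id, model$reactions$id)
  if (is.na(i)) stop("unknown objective reaction: ", objective_id)
  S <- stoich_matrix(model)
  n <- nrow(model$reactions)
  obj <- numeric(n)
  obj[i] <- 1
  sol <- lp_solve(obj, S, rep(0, nrow(S)),
                  model$reactions$lower_bound, model$reactions$upper_bound,
                  maximize = direction == "max")
  .log_debug("solve_fba[", model$id, ", ", objective_id, ", ", direction,
             "]: ", sol$status,
             if (sol$status == "optimal") paste0(", value ", sol$value))
  if (sol$status != "optimal") {
    return(.flux_state(NULL, objective_id, NA_real_, sol$status))
  }
  .flux_state(stats::setNames(sol$x, model$reactions$id),
              objective_id, sol$value, "optimal")
}

#' Solve FBA with reactions fixed at given fluxes
#'
#' Clamps both bounds of each named reaction to the stated value and solves
#' [solve_fba()]. The input model is not modified.
#'
#' @param model a `metabolic_model`.
#' @param fixed named list or numeric vector, reaction id to flux value.
#'   Values must be finite and inside the reaction's original bounds.
#' @param objective_id reaction whose flux is optimized.
#' @param direction `"max"` or `"min"`.
#' @return A `flux_state`.
#' @export
solve_fixed <- function(model, fixed, objective_id,
                        direction = c("max", "min")) {
  direction <- match.arg(direction)
  fixed <- unlist(fixed)
  if (length(fixed)) {
    idx <- match(names(fixed), model$reactions$id)
    if (anyNA(idx)) {
      stop("cannot fix unknown reaction(s): ",
           paste(names(fixed)[is.na(idx)], collapse = ", "))
    }
    if (any(!is.finite(fixed))) stop("fixed flux values must be finite")
    out <- fixed < model$reactions$lower_bound[idx] - 1e-9 |
           fixed > model$reactions$upper_bound[idx] + 1e-9
    if (any(out)) {
      stop("fixed value outside original bounds for reaction(s): ",
           paste(names(fixed)[out], collapse = ", "))
    }
    for (k in seq_along(fixed)) {
      model$reactions$lower_bound[idx[k]] <- fixed[[k]]
      model$reactions$upper_bound[idx[k]] <- fixed[[k]]
    }
  }
  solve_fba(model, objective_id, direction)
}

#' Lexicographic two-objective optimization
#'
#' Maximizes the primary objective under the given fixed fluxes, then fixes
#' the primary flux at its optimum (to within an absolute tolerance of
#' `1e-6 * max(1, |optimum|)`) and maximizes the secondary objective.
#'
#' @param model a `metabolic_model`.
#' @param primary_id,secondary_id distinct reaction ids.
#' @param fixed named list of reaction fluxes to clamp, as in [solve_fixed()].
#' @return A list with `primary` and `secondary` optima (both `NA` when the
#'   primary stage is not optimal) and `state`, the final `flux_state`.
#' @export
lexicographic_opt <- function(model, primary_id, secondary_id,
                              fixed = list()) {
  if (identical(primary_id, secondary_id)) {
    stop("primary and secondary objectives must differ")
  }
  if (is.na(match(secondary_id, model$reactions$id))) {
    stop("unknown objective reaction: ", secondary_id)
  }
  s1 <- solve_fixed(model, fixed, primary_id, "max")
  if (s1$status != "optimal") {
    return(list(primary = NA_real_, secondary = NA_real_, state = s1))
  }
  opt <- s1$objective_value
  tol <- 1e-6 * max(1, abs(opt))
  i <- match(primary_id, model$reactions$id)
  model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i],
                                        opt - tol)
  model$reactions$upper_bound[i] <- min(model$reactions$upper_bound[i],
                                        opt + tol)
  s2 <- solve_fixed(model, fixed, secondary_id, "max")
  if (s2$status != "optimal") {
    return(list(primary = opt, secondary = NA_real_, state = s2))
  }
  list(primary = opt, secondary = s2$objective_value, state = s2)
}

#' Parsimonious FBA
#'
#' Among the flux distributions attaining the FBA optimum of
#' `objective_id`, returns one minimizing the total absolute flux
#' (the standard flux-split LP with `v = p - q`, `p, q >= 0`). Useful
#' because plain FBA optima are generally degenerate and solver-dependent.
#'
#' @param model a `metabolic_model`.
#' @param objective_id reaction whose flux is first maximized.
#' @return A `flux_state` whose `objective_value` is the FBA optimum; the
#'   total absolute flux of the returned distribution is attached as
#'   attribute `"total_flux"`.
#' @export
pfba_solve <- function(model, objective_id) {
  s1 <- solve_fba(model, objective_id, "max")
  if (s1$status != "optimal") return(s1)
  opt <- s1$objective_value

  S <- stoich_matrix(model)
  m <- nrow(S); n <- ncol(S)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  big <- 1e6
  lbc <- pmax(lb, -big); ubc <- pmin(ub, big)

  # variables: p (forward part), q (reverse part), s (bound slacks)
  # rows: S p - S q = 0 ; p - q - s = lb ; flux(objective) = opt
  A <- cbind(S, -S, matrix(0, m, n))
  Aslack <- cbind(diag(n), -diag(n), -diag(n))
  e <- numeric(3 * n); e[match(objective_id, model$reactions$id)] <- 1
  e[n + match(objective_id, model$reactions$id)] <- -1
  A <- rbind(A, Aslack, e)
  b <- c(rep(0, m), lbc, opt)
  lo <- c(rep(0, n), rep(0, n), rep(0, n))
  hi <- c(pmax(ubc, 0), pmax(-lbc, 0), ubc - lbc)
  objv <- c(rep(1, 2 * n), rep(0, n))
  sol <- lp_solve(objv, A, b, lo, hi, maximize = FALSE)
  if (sol$status != "optimal") {
    # fall back to the plain FBA solution rather than failing the run
    .log_debug("pfba_solve: split LP ", sol$status, "; returning plain FBA")
    return(s1)
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  out <- .flux_state(stats::setNames(v, model$reactions$id),
                     objective_id, opt, "optimal")
  attr(out, "total_flux") <- sum(abs(v))
  out
}
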