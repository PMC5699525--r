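# Toy metabolic networks with analytically known optima, plus an exact
# vertex-enumeration LP oracle. Together they make every pipeline stage
# testable without downloading any genome-scale model.
#
# Conventions mirror genome-scale practice: default bound magnitude 1000,
# default substrate uptake 10 mmol/gDW/h.

#' Canonical branched toy network
#'
#' A 6-reaction, 4-metabolite network with a branch point at metabolite A:
#' glucose uptake `EX_glc` (bounds `[-uptake_limit, 1000]`), transport `T1`
#' (glc_e -> a_c), biomass branch `RB` (a_c -> b_c), product branch `RP`
#' (a_c -> p_c), biomass `BIO` (0.8 b_c + 0.2 p_c ->, the objective) and a
#' product demand `DM_p` (p_c ->, bounds `[0, 1000]`).
#'
#' With the defaults, growth maximization gives BIO = 10 (RB = 8, RP = 2)
#' and product maximization gives DM_p = 10 (RP = 10), so UPA on `p_c`
#' returns the single candidate RP with Ratio 5 and Yield 10.
#'
#' @param uptake_limit substrate uptake capacity (mmol/gDW/h, default 10).
#' @param biomass_stoichiometry named coefficients of the biomass equation
#'   over precursors `b_c` and/or `p_c` (default `c(b_c = 0.8, p_c = 0.2)`).
#' @param step_coefficients named products-per-A coefficients for the two
#'   branches, `c(RB = 1, RP = 1)` by default (perturbed by the randomized
#'   variants).
#' @return A `metabolic_model`.
#' @export
make_branch_model <- function(uptake_limit = 10,
                              biomass_stoichiometry = c(b_c = 0.8, p_c = 0.2),
                              step_coefficients = c(RB = 1, RP = 1)) {
  stopifnot(uptake_limit > 0, all(biomass_stoichiometry > 0),
            all(step_coefficients > 0))
  mets <- data.frame(
    id = c("glc_e", "a_c", "b_c", "p_c"),
    name = c("Glucose (extracellular)", "Precursor A", "Biomass precursor B",
             "Product P"),
    compartment = c("e", "c", "c", "c"),
    stringsAsFactors = FALSE)
  bio <- -biomass_stoichiometry
  rxns <- data.frame(
    id = c("EX_glc", "T1", "RB", "RP", "BIO", "DM_p"),
    name = c("Glucose exchange", "Glucose transport", "Biomass branch",
             "Product branch", "Biomass", "Product demand"),
    lower_bound = c(-uptake_limit, 0, 0, 0, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000, 1000, 1000),
    objective_coefficient = c(0, 0, 0, 0, 1, 0),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_glc = c(glc_e = -1),
    T1 = c(glc_e = -1, a_c = 1),
    RB = c(a_c = -1, b_c = unname(step_coefficients[["RB"]])),
    RP = c(a_c = -1, p_c = unname(step_coefficients[["RP"]])),
    BIO = bio,
    DM_p = c(p_c = -1))
  gpr <- list(
    T1 = parse_gpr("gT1"),
    RB = parse_gpr("gRB1 and gRB2"),
    RP = parse_gpr("(gRP1 and gRP2) or gRP3"))
  metabolic_model("branch1", mets, rxns, stoich, gpr)
}

#' Linear chain toy network
#'
#' Uptake feeding a chain `m1 -> m2 -> ... -> m_n` whose terminus is the
#' sole biomass precursor. Every interior metabolite's synthesis flux is
#' already maximal at the growth optimum, so UPA targeting any interior
#' metabolite returns an empty candidate set: its overproduction requires
#' only down-regulation of the downstream step.
#'
#' @param n_steps chain length, at least 2.
#' @param uptake_limit substrate uptake capacity (default 10).
#' @return A `metabolic_model` with id `LIN-<n_steps>`.
#' @export
make_linear_model <- function(n_steps = 3, uptake_limit = 10) {
  if (n_steps < 2) stop("n_steps must be at least 2")
  ms <- paste0("m", seq_len(n_steps))
  mets <- data.frame(
    id = c("s_e", ms),
    name = c("Substrate (extracellular)", paste("Intermediate", ms)),
    compartment = c("e", rep("c", n_steps)),
    stringsAsFactors = FALSE)
  steps <- paste0("S", seq_len(n_steps - 1L))
  rxns <- data.frame(
    id = c("EX_s", "TS", steps, "BIO"),
    name = c("Substrate exchange", "Substrate transport",
             paste("Chain step", steps), "Biomass"),
    lower_bound = c(-uptake_limit, rep(0, n_steps + 1L)),
    upper_bound = rep(1000, n_steps + 2L),
    objective_coefficient = c(rep(0, n_steps + 1L), 1),
    stringsAsFactors = FALSE)
  stoich <- c(
    list(EX_s = c(s_e = -1), TS = c(s_e = -1, m1 = 1)),
    stats::setNames(lapply(seq_len(n_steps - 1L), function(k) {
      stats::setNames(c(-1, 1), c(ms[k], ms[k + 1L]))
    }), steps),
    list(BIO = stats::setNames(-1, ms[n_steps])))
  gpr <- stats::setNames(lapply(steps, function(s) {
    parse_gpr(paste0("g", s))
  }), steps)
  metabolic_model(paste0("LIN-", n_steps), mets, rxns, stoich, gpr)
}

#' Branched toy network with an obligate degradation pathway
#'
#' The branch network of [make_branch_model()] extended by a degradation
#' pathway for a secondary product `x_c`: synthesis `SYN`
#' (p_c -> x_c + dcp_c) emits a coupling metabolite `dcp_c` whose only
#' consumer is the degradation reaction `DEG` (x_c + dcp_c -> waste_e), so
#' every unit of `x_c` produced is obligately degraded and the metabolite
#' can never accumulate. UPA targeting `x_c` therefore returns an empty
#' result (theoretical maximum yield 0) and clamping any synthesis flux
#' re-verifies to yield 0, while targeting `p_c` in the same model still
#' reproduces the plain branch result.
#'
#' The stoichiometric coupling is the steady-state encoding of a degradation
#' flux that scales with production; a fixed lower bound cannot express
#' that.
#'
#' @inheritParams make_branch_model
#' @return A `metabolic_model` with id `branch1-deg`.
#' @export
make_degradation_model <- function(uptake_limit = 10) {
  model <- make_branch_model(uptake_limit = uptake_limit)
  model$id <- "branch1-deg"
  model$metabolites <- rbind(model$metabolites, data.frame(
    id = c("x_c", "dcp_c", "waste_e"),
    name = c("Secondary product X", "Degradation coupling",
             "Degradation waste"),
    compartment = c("c", "c", "e"),
    stringsAsFactors = FALSE))
  model <- add_reaction(model, "SYN", "Secondary product synthesis",
                        c(p_c = -1, x_c = 1, dcp_c = 1), 0, 1000,
                        gpr = parse_gpr("gSYN"))
  model <- add_reaction(model, "DEG", "Obligate degradation",
                        c(x_c = -1, dcp_c = -1, waste_e = 1), 0, 1000)
  add_reaction(model, "EX_waste", "Waste exchange", c(waste_e = -1), 0, 1000)
}

#' Parallel-path toy network
#'
#' Two equivalent internal routes `P1`, `P2` from A to the biomass
#' precursor. Plain FBA may place the flux on either route; parsimonious
#' FBA returns a distribution whose total absolute flux equals the
#' enumerable minimum.
#'
#' @inheritParams make_branch_model
#' @return A `metabolic_model` with id `parallel1`.
#' @export
make_parallel_model <- function(uptake_limit = 10) {
  mets <- data.frame(
    id = c("glc_e", "a_c", "b_c"),
    name = c("Glucose (extracellular)", "Precursor A", "Biomass precursor B"),
    compartment = c("e", "c", "c"),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_glc", "T1", "P1", "P2", "BIO"),
    name = c("Glucose exchange", "Glucose transport", "Route 1", "Route 2",
             "Biomass"),
    lower_bound = c(-uptake_limit, 0, 0, 0, 0),
    upper_bound = rep(1000, 5),
    objective_coefficient = c(0, 0, 0, 0, 1),
    stringsAsFactors = FALSE)
  stoich <- list(
    EX_glc = c(glc_e = -1),
    T1 = c(glc_e = -1, a_c = 1),
    P1 = c(a_c = -1, b_c = 1),
    P2 = c(a_c = -1, b_c = 1),
    BIO = c(b_c = -1))
  metabolic_model("parallel1", mets, rxns, stoich,
                  list(P1 = parse_gpr("gP1"), P2 = parse_gpr("gP2")))
}

#' Randomized toy variant
#'
#' Perturbs the numeric parameters of a canonical topology — uptake limit,
#' branch stoichiometric coefficients, biomass composition — while leaving
#' the topology untouched, so the vertex-enumeration oracle remains cheap
#' and the qualitative solution structure is preserved. The caller's RNG
#' state is left unchanged.
#'
#' @param seed integer seed for the variant.
#' @param topology `"branch"` or `"parallel"`.
#' @return A `metabolic_model`.
#' @export
random_toy_model <- function(seed, topology = c("branch", "parallel")) {
  topology <- match.arg(topology)
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed)
  uptake <- round(stats::runif(1, 5, 15), 3)
  if (topology == "branch") {
    bio <- c(b_c = round(stats::runif(1, 0.3, 1.2), 3),
             p_c = round(stats::runif(1, 0.1, 0.8), 3))
    steps <- c(RB = round(stats::runif(1, 0.5, 2), 3),
               RP = round(stats::runif(1, 0.5, 2), 3))
    m <- make_branch_model(uptake_limit = uptake,
                           biomass_stoichiometry = bio,
                           step_coefficients = steps)
  } else {
    m <- make_parallel_model(uptake_limit = uptake)
  }
  m$id <- paste0(m$id, "-seed", seed)
  m
}

#' Exact LP optimum by vertex enumeration
#'
#' Independent verification oracle for [solve_fba()]: enumerates the basic
#' feasible solutions (vertices) of `{S v = 0, lb <= v <= ub}` by trying
#' every full-rank column basis with the remaining reactions pinned at
#' either bound, and returns the best vertex for the stated objective.
#' Intended for models of at most 12 reactions; complexity is exponential.
#'
#' @param model a `metabolic_model` with at most 12 reactions.
#' @param objective_id reaction whose flux is optimized.
#' @param direction `"max"` or `"min"`.
#' @return A `flux_state` with status `"optimal"`, `"infeasible"` or
#'   `"unbounded"` (the latter when the best vertex presses against the cap
#'   substituted for an infinite bound).
#' @export
oracle_solve <- function(model, objective_id, direction = c("max", "min")) {
  direction <- match.arg(direction)
  n <- nrow(model$reactions)
  if (n > 12L) stop("oracle_solve is limited to models with <= 12 reactions")
  i_obj <- match(objective_id, model$reactions$id)
  if (is.na(i_obj)) stop("unknown objective reaction: ", objective_id)
  big <- 1e6
  lb0 <- model$reactions$lower_bound
  ub0 <- model$reactions$upper_bound
  lb <- pmax(lb0, -big)
  ub <- pmin(ub0, big)
  if (any(lb > ub)) {
    return(.flux_state(NULL, objective_id, NA_real_, "infeasible"))
  }
  S <- stoich_matrix(model)
  r <- qr(S)$rank
  sgn <- if (direction == "max") 1 else -1
  tol <- 1e-7 * max(1, max(abs(ub), abs(lb)))

  best_val <- -Inf
  best_v <- NULL
  consider <- function(v) {
    if (max(abs(S %*% v)) > tol) return()
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    val <- sgn * v[i_obj]
    if (val > best_val + 1e-12) {
      best_val <<- val
      best_v <<- v
    }
  }
  if (r == 0L) {
    # no coupling at all: each flux independently at its best bound
    v <- ifelse(sgn * (seq_len(n) == i_obj) > 0, ub, lb)
    consider(v)
  } else {
    bases <- utils::combn(n, r)
    for (b in seq_len(ncol(bases))) {
      B <- bases[, b]
      qrB <- qr(S[, B, drop = FALSE])
      if (qrB$rank < r) next
      N <- setdiff(seq_len(n), B)
      for (mask in 0:(2^length(N) - 1L)) {
        vN <- lb[N]
        if (length(N)) {
          up <- bitwAnd(mask, bitwShiftL(1L, seq_along(N) - 1L)) != 0L
          vN[up] <- ub[N][up]
        }
        rhs <- if (length(N)) -S[, N, drop = FALSE] %*% vN else
          matrix(0, nrow(S), 1)
        vB <- qr.coef(qrB, rhs)
        if (anyNA(vB)) next
        v <- numeric(n)
        v[N] <- vN
        v[B] <- vB
        consider(v)
      }
    }
  }
  if (is.null(best_v)) {
    return(.flux_state(NULL, objective_id, NA_real_, "infeasible"))
  }
  capped <- (!is.finite(ub0) & best_v > big - 1e-3 * big) |
            (!is.finite(lb0) & best_v < -big + 1e-3 * big)
  if (any(capped)) {
    return(.flux_state(NULL, objective_id, NA_real_, "unbounded"))
  }
  .flux_state(stats::setNames(best_v, model$reactions$id), objective_id,
              best_v[i_obj], "optimal")
}
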