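# Up-regulated pathway analysis (UPA).
#
# The procedure identifies single-reaction overexpression targets that
# directly contribute to overproducing a chosen metabolite:
#
#   1. Solve the wild-type network (biomass objective, product drain closed)
#      giving flux_wt, and the maximum-yield network (product-demand
#      objective) giving flux_opt; reactions whose flux magnitude must
#      increase between the two states are the up-regulated candidates.
#   2. Re-verify each candidate by clamping it at its flux_opt in the
#      wild-type network, maximizing growth, and reading the product yield
#      attainable at that growth optimum; candidates with zero yield are
#      only indirectly related to production and are dropped.
#   3. Rank survivors by their up-regulation Ratio = |flux_opt| / |flux_wt|
#      (infinite for newly activated reactions) and group neighbouring
#      Ratio levels into metabolic modules.

#' Analysis options for UPA
#'
#' @param eps_flux numeric > 0; fluxes with magnitude below this are treated
#'   as zero, and an up-regulation must exceed it to count (default `1e-6`,
#'   the LP reporting precision).
#' @param eps_yield numeric > 0; candidates must achieve a re-verified yield
#'   above this to be kept (default `1e-6`).
#' @param eps_rel numeric > 0; finite Ratios must exceed `1 + eps_rel`
#'   (default `1e-6`).
#' @param module_rel_tol numeric > 0; relative gap between consecutive
#'   ranked Ratios above which a new metabolic module starts (default
#'   `0.05`, i.e. 5 percent).
#' @param use_pfba logical; when `TRUE` the wild-type and maximum-yield
#'   states are computed with [pfba_solve()] instead of plain FBA, which
#'   removes the solver dependence of degenerate optima (default `FALSE`).
#' @param bound_overrides named list of `c(lb, ub)` reaction bound
#'   replacements applied before any solve (growth/uptake conditions).
#' @return An object of class `upa_options`.
#' @export
upa_options <- function(eps_flux = 1e-6, eps_yield = 1e-6, eps_rel = 1e-6,
                        module_rel_tol = 0.05, use_pfba = FALSE,
                        bound_overrides = list()) {
  stopifnot(eps_flux > 0, eps_yield > 0, eps_rel > 0, module_rel_tol > 0,
            is.logical(use_pfba))
  structure(list(eps_flux = eps_flux, eps_yield = eps_yield,
                 eps_rel = eps_rel, module_rel_tol = module_rel_tol,
                 use_pfba = use_pfba, bound_overrides = bound_overrides),
            class = "upa_options")
}

.empty_candidates <- function() {
  data.frame(rank = integer(), reaction_id = character(),
             reaction_name = character(), genes = I(list()),
             formula = character(), flux_wt = numeric(),
             flux_opt = numeric(), ratio = numeric(),
             yield_value = numeric(), module = integer(),
             stringsAsFactors = FALSE)
}

.upa_result <- function(target_metabolite, demand_id, biomass_id,
                        theoretical_max_yield, candidates, options) {
  structure(list(target_metabolite = target_metabolite,
                 demand_id = demand_id, biomass_id = biomass_id,
                 theoretical_max_yield = theoretical_max_yield,
                 candidates = candidates, options = options),
            class = "upa_result")
}

#' @export
print.upa_result <- function(x, ...) {
  cat("UPA result for target", x$target_metabolite,
      "(demand", paste0(x$demand_id, ","),
      "biomass", paste0(x$biomass_id, ")\n"))
  cat("  theoretical maximum yield:", format(x$theoretical_max_yield), "\n")
  if (nrow(x$candidates) == 0L) {
    cat("  no overexpression candidates\n")
  } else {
    df <- x$candidates
    df$genes <- vapply(df$genes, paste, "", collapse = ";")
    print(df[, c("rank", "reaction_id", "genes", "flux_wt", "flux_opt",
                 "ratio", "yield_value", "module")], row.names = FALSE)
  }
  invisible(x)
}

#' Ensure the target metabolite has a demand drain
#'
#' An internal metabolite can only be an FBA objective through an
#' irreversible drain consuming it. An existing demand or sink reaction
#' consuming exactly the target with bounds `[0, U]` is reused; otherwise a
#' reaction `DM_<met>` with bounds `[0, 1000]` is appended. Idempotent.
#'
#' @param model a `metabolic_model`.
#' @param metabolite_id a metabolite id as stored in the model.
#' @return A list with the (possibly augmented) `model` and `demand_id`.
#' @export
ensure_demand <- function(model, metabolite_id) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite: ", metabolite_id)
  }
  for (i in seq_len(nrow(model$reactions))) {
    if (!model$reactions$boundary_kind[i] %in% c("demand", "sink")) next
    st <- model$stoichiometry[[model$reactions$id[i]]]
    st <- st[st != 0]
    if (length(st) == 1L && names(st) == metabolite_id && st < 0 &&
        model$reactions$lower_bound[i] == 0 &&
        model$reactions$upper_bound[i] > 0) {
      return(list(model = model, demand_id = model$reactions$id[i]))
    }
  }
  dm <- paste0("DM_", metabolite_id)
  while (dm %in% model$reactions$id) dm <- paste0(dm, "_demand")
  model <- add_reaction(model, dm, paste("Demand for", metabolite_id),
                        stats::setNames(-1, metabolite_id), 0, 1000)
  list(model = model, demand_id = dm)
}

.state_solver <- function(model, objective_id, options) {
  if (isTRUE(options$use_pfba)) pfba_solve(model, objective_id)
  else solve_fba(model, objective_id, "max")
}

#' Wild-type flux state
#'
#' Growth-maximal flux distribution of the unengineered network: the target
#' demand reaction is closed (both bounds 0) and the biomass reaction is
#' maximized. These fluxes are the `flux_wt` of the analysis.
#'
#' @param model a `metabolic_model` (demand already present).
#' @param biomass_id biomass reaction id.
#' @param demand_id target demand reaction id (closed during this solve).
#' @param options a [upa_options()] object.
#' @return A `flux_state`. An infeasible wild type aborts with a diagnostic.
#' @export
wild_type_fluxes <- function(model, biomass_id, demand_id,
                             options = upa_options()) {
  model <- apply_bounds(model, stats::setNames(list(c(0, 0)), demand_id))
  st <- .state_solver(model, biomass_id, options)
  if (st$status != "optimal") {
    stop("wild-type model is ", st$status,
         "; check uptake bounds and the biomass selection")
  }
  st
}

#' Maximum-yield flux state
#'
#' Flux distribution maximizing the target demand reaction; its objective
#' value is the theoretical maximum yield and its fluxes are the `flux_opt`
#' of the analysis.
#'
#' @inheritParams wild_type_fluxes
#' @return A `flux_state`.
#' @export
optimum_fluxes <- function(model, demand_id, options = upa_options()) {
  st <- .state_solver(model, demand_id, options)
  if (st$status == "unbounded") {
    stop("maximum-yield problem is unbounded; review exchange and demand ",
         "bounds of the model")
  }
  if (st$status != "optimal") {
    stop("maximum-yield model is ", st$status)
  }
  st
}

#' Detect up-regulated reactions
#'
#' Compares the wild-type and maximum-yield flux states and returns the
#' internal reactions whose flux magnitude must increase to reach maximum
#' production. Boundary reactions (exchange, demand, sink) and the biomass
#' reaction are never candidates, and a flux that reverses sign between the
#' two states counts as rewiring, not up-regulation.
#'
#' @param flux_wt,flux_opt optimal `flux_state`s from [wild_type_fluxes()]
#'   and [optimum_fluxes()].
#' @param model the analyzed `metabolic_model`.
#' @param options a [upa_options()] object.
#' @return Character vector of candidate reaction ids.
#' @export
detect_upregulated <- function(flux_wt, flux_opt, model,
                               options = upa_options()) {
  stopifnot(flux_wt$status == "optimal", flux_opt$status == "optimal")
  eps <- options$eps_flux
  internal <- model$reactions$id[model$reactions$boundary_kind == "internal"]
  keep <- vapply(internal, function(rid) {
    w <- flux_wt$fluxes[[rid]]
    o <- flux_opt$fluxes[[rid]]
    sw <- if (abs(w) <= eps) 0 else sign(w)
    so <- if (abs(o) <= eps) 0 else sign(o)
    if (sw * so < 0) return(FALSE)
    abs(o) > abs(w) + eps
  }, logical(1))
  out <- internal[keep]
  .log_debug("detect_upregulated: ", length(out), " candidate(s): ",
             paste(out, collapse = ", "))
  out
}

#' Re-verify a candidate's contribution to product yield
#'
#' Clamps the candidate reaction at its maximum-yield flux in the wild-type
#' network, maximizes biomass, then maximizes the product demand at the
#' growth optimum (lexicographic solve). The returned secondary optimum is
#' the candidate's `Yield`; a clamp that makes the network infeasible maps
#' to yield 0 with attribute `infeasible = TRUE` rather than aborting.
#'
#' @param model a `metabolic_model` with open demand.
#' @param candidate_id internal reaction to clamp.
#' @param v_opt finite flux value to clamp it at (its `flux_opt`).
#' @param biomass_id,demand_id objective reactions of the two stages.
#' @param options a [upa_options()] object.
#' @return Numeric yield with logical attribute `"infeasible"`.
#' @export
verify_yield <- function(model, candidate_id, v_opt, biomass_id, demand_id,
                         options = upa_options()) {
  stopifnot(is.finite(v_opt))
  i <- match(candidate_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", candidate_id)
  if (model$reactions$boundary_kind[i] != "internal") {
    stop("candidate must be an internal reaction: ", candidate_id)
  }
  lex <- tryCatch(
    lexicographic_opt(model, biomass_id, demand_id,
                      fixed = stats::setNames(list(v_opt), candidate_id)),
    error = function(e) NULL)
  if (is.null(lex) || lex$state$status != "optimal" ||
      !is.finite(lex$secondary)) {
    .log_debug("verify_yield[", candidate_id, " = ", v_opt,
               "]: infeasible, yield 0")
    return(structure(0, infeasible = TRUE))
  }
  .log_debug("verify_yield[", candidate_id, " = ", v_opt, "]: yield ",
             lex$secondary)
  structure(max(lex$secondary, 0), infeasible = FALSE)
}

#' Filter and rank candidate records
#'
#' Drops records whose yield does not exceed `eps_yield` or whose Ratio is
#' not above 1 (newly activated reactions have Ratio `Inf` and always
#' qualify on that axis), then sorts by Ratio descending (`Inf` first),
#' yield descending, reaction id ascending, and assigns 1-based ranks.
#'
#' @param records data.frame with columns `reaction_id`, `reaction_name`,
#'   `genes` (list), `formula`, `flux_wt`, `flux_opt`, `ratio`,
#'   `yield_value`.
#' @param options a [upa_options()] object.
#' @return The filtered, ordered data.frame with `rank` and `module`
#'   columns (`module` is `NA` until [group_modules()]).
#' @export
rank_candidates <- function(records, options = upa_options()) {
  if (is.null(records) || nrow(records) == 0L) {
    warning("no candidate records to rank")
    return(.empty_candidates())
  }
  keep <- records$yield_value > options$eps_yield &
    (is.infinite(records$ratio) | records$ratio > 1 + options$eps_rel)
  dropped <- records$reaction_id[!keep]
  if (length(dropped)) {
    .log_debug("rank_candidates: filtered out ",
               paste(dropped, collapse = ", "))
  }
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) {
    warning("all candidates filtered out (yield or ratio below threshold)")
    return(.empty_candidates())
  }
  ord <- order(-records$ratio, -records$yield_value, records$reaction_id)
  records <- records[ord, , drop = FALSE]
  records$rank <- seq_len(nrow(records))
  records$module <- NA_integer_
  rownames(records) <- NULL
  records[, c("rank", "reaction_id", "reaction_name", "genes", "formula",
              "flux_wt", "flux_opt", "ratio", "yield_value", "module")]
}

#' Genes associated with a reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction_id one reaction id.
#' @return Sorted, duplicate-free character vector of gene ids; empty for
#'   spontaneous reactions.
#' @export
genes_for <- function(model, reaction_id) {
  if (is.na(match(reaction_id, model$reactions$id))) {
    stop("unknown reaction id: ", reaction_id)
  }
  gpr_genes(model$gpr[[reaction_id]])
}

#' Group ranked candidates into Ratio-level metabolic modules
#'
#' Candidates with similar up-regulation Ratios tend to sit adjacently in
#' the metabolic map, so Ratio levels delineate functional modules. Walking
#' the candidates in rank order, a new module starts whenever the relative
#' gap between consecutive finite Ratios exceeds `module_rel_tol`; all
#' infinite Ratios form the leading module. Labels are 1-based.
#'
#' @param result a `upa_result` with ranked candidates.
#' @param options a [upa_options()] object.
#' @return The `upa_result` with the `module` column filled in.
#' @export
group_modules <- function(result, options = upa_options()) {
  stopifnot(inherits(result, "upa_result"))
  r <- result$candidates$ratio
  n <- length(r)
  if (n == 0L) return(result)
  module <- integer(n)
  label <- 0L
  prev <- NULL
  for (i in seq_len(n)) {
    if (is.infinite(r[i])) {
      if (label == 0L) label <- 1L
      module[i] <- 1L
      next
    }
    if (is.null(prev)) {
      label <- label + 1L
    } else if ((prev - r[i]) / prev > options$module_rel_tol) {
      label <- label + 1L
    }
    module[i] <- label
    prev <- r[i]
  }
  result$candidates$module <- module
  result
}

# biomass auto-selection: the unique reaction with a nonzero objective
# coefficient; anything else requires an explicit choice.
.select_biomass <- function(model, biomass_id) {
  nz <- model$reactions$id[model$reactions$objective_coefficient != 0]
  if (!is.null(biomass_id)) {
    if (is.na(match(biomass_id, model$reactions$id))) {
      stop("unknown biomass reaction: ", biomass_id)
    }
    return(biomass_id)
  }
  if (length(nz) == 0L) {
    stop("model declares no objective reaction; supply biomass_id explicitly")
  }
  if (length(nz) > 1L) {
    stop("model declares several objective reactions (",
         paste(nz, collapse = ", "),
         "); supply biomass_id to choose the growth function")
  }
  nz
}

#' Run up-regulated pathway analysis
#'
#' The full procedure: resolve the target metabolite, ensure it has a demand
#' drain, compute the wild-type (demand closed) and maximum-yield flux
#' states, detect up-regulated internal reactions, re-verify each by
#' clamping it at its optimum flux and reading the growth-coupled product
#' yield, filter, rank by Ratio, and group Ratio levels into metabolic
#' modules.
#'
#' @param model a `metabolic_model`.
#' @param target_metabolite metabolite id in either dialect
#'   (`"frdp[c]"` or `"frdp_c"`).
#' @param options a [upa_options()] object.
#' @param biomass_id biomass reaction id; `NULL` auto-selects the unique
#'   objective reaction and errors when the model declares several growth
#'   functions.
#' @return A `upa_result` with elements `target_metabolite`, `demand_id`,
#'   `biomass_id`, `theoretical_max_yield`, `candidates` (ranked
#'   data.frame) and `options`. A target that cannot accumulate any flux
#'   yields an empty candidate table with a warning.
#' @examples
#' model <- make_branch_model()
#' res <- run_upa(model, "p[c]")
#' res$candidates[, c("rank", "reaction_id", "ratio", "yield_value")]
#' @export
run_upa <- function(model, target_metabolite, options = upa_options(),
                    biomass_id = NULL) {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(options, "upa_options"))
  model <- apply_bounds(model, options$bound_overrides)
  met <- normalize_metabolite_id(target_metabolite, model)
  biomass <- .select_biomass(model, biomass_id)
  aug <- ensure_demand(model, met)
  model <- aug$model
  demand <- aug$demand_id
  .log_debug("run_upa: target ", met, ", demand ", demand, ", biomass ",
             biomass)

  wt <- wild_type_fluxes(model, biomass, demand, options)
  opt <- optimum_fluxes(model, demand, options)
  tmax <- opt$objective_value

  if (tmax <= options$eps_yield) {
    warning("target '", met, "' cannot accumulate under the given bounds ",
            "(theoretical maximum yield ", format(tmax),
            "); returning an empty result")
    return(.upa_result(met, demand, biomass, tmax, .empty_candidates(),
                       options))
  }

  cand_ids <- detect_upregulated(wt, opt, model, options)
  if (length(cand_ids) == 0L) {
    warning("no up-regulated internal reactions for target '", met, "'")
    return(.upa_result(met, demand, biomass, tmax, .empty_candidates(),
                       options))
  }

  records <- data.frame(
    reaction_id = cand_ids,
    reaction_name = model$reactions$name[match(cand_ids,
                                               model$reactions$id)],
    stringsAsFactors = FALSE)
  records$genes <- I(lapply(cand_ids, genes_for, model = model))
  records$formula <- vapply(cand_ids, reaction_formula, "", model = model)
  records$flux_wt <- unname(wt$fluxes[cand_ids])
  records$flux_opt <- unname(opt$fluxes[cand_ids])
  records$ratio <- ifelse(abs(records$flux_wt) > options$eps_flux,
                          abs(records$flux_opt) / abs(records$flux_wt),
                          Inf)
  records$yield_value <- vapply(seq_along(cand_ids), function(k) {
    as.numeric(verify_yield(model, cand_ids[k], records$flux_opt[k],
                            biomass, demand, options))
  }, numeric(1))

  ranked <- withCallingHandlers(
    rank_candidates(records, options),
    warning = function(w) {
      # rank_candidates' empty-input warning is re-raised with target context
      invokeRestart("muffleWarning")
    })
  if (nrow(ranked) == 0L) {
    warning("no candidate passes the Yield/Ratio filter for target '",
            met, "'")
  }
  result <- .upa_result(met, demand, biomass, tmax, ranked, options)
  group_modules(result, options)
}
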