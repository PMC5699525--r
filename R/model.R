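# In-memory representation of a constraint-based metabolic model.
#
# A model is the data FBA needs and nothing more: metabolites, reactions with
# bounds and objective coefficients, per-reaction stoichiometry, and
# gene-protein-reaction (GPR) associations. Flux units follow the convention
# of genome-scale reconstructions, mmol / gDW / h.

#' Construct a metabolic model
#'
#' Builds and validates the container used by all analyses in this package.
#' Reaction boundary kinds are classified automatically: the reaction(s)
#' carrying a nonzero objective coefficient are `"biomass"`; reactions with
#' metabolites on only one side are `"demand"`, `"sink"` or `"exchange"`
#' according to their `DM_` / `SK_` / `EX_` id prefix (defaulting to
#' exchange); everything else is `"internal"`. Only internal reactions are
#' ever considered overexpression candidates.
#'
#' @param id model identifier.
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `objective_coefficient`.
#' @param stoichiometry named list (one element per reaction id) of named
#'   numeric vectors mapping metabolite id to signed coefficient
#'   (negative = consumed).
#' @param gpr named list of GPR expression trees as returned by
#'   [parse_gpr()]; reactions may be absent or `NULL` (spontaneous).
#'
#' @return An object of class `metabolic_model`.
#' @seealso [read_sbml()], [make_branch_model()]
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            gpr = list()) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "name", "compartment") %in% names(metabolites)),
            all(c("id", "name", "lower_bound", "upper_bound",
                  "objective_coefficient") %in% names(reactions)))
  gpr <- gpr[!vapply(gpr, is.null, logical(1))]
  genes <- sort(unique(unlist(lapply(gpr, gpr_genes))))
  if (is.null(genes)) genes <- character()
  model <- structure(
    list(id = id,
         metabolites = metabolites,
         reactions = reactions,
         stoichiometry = stoichiometry,
         gpr = gpr,
         genes = genes),
    class = "metabolic_model")
  model$reactions$boundary_kind <- classify_boundary(model)
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks the structural invariants the analyses rely on: unique identifiers,
#' consistent bounds, and stoichiometry referring only to declared
#' metabolites. Called by every constructor; exported for models assembled by
#' hand.
#'
#' @param model a `metabolic_model`.
#' @return `model`, invisibly. Errors describe the first violated invariant.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (nrow(model$reactions) == 0L) {
    stop("structural error: model '", model$id, "' declares no reactions")
  }
  if (anyDuplicated(model$metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(model$metabolites$id[duplicated(model$metabolites$id)]),
               collapse = ", "))
  }
  if (anyDuplicated(model$reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(model$reactions$id[duplicated(model$reactions$id)]),
               collapse = ", "))
  }
  bad <- model$reactions$lower_bound > model$reactions$upper_bound
  if (any(bad)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(model$reactions$id[bad], collapse = ", "))
  }
  missing_st <- setdiff(model$reactions$id, names(model$stoichiometry))
  if (length(missing_st)) {
    stop("no stoichiometry for reaction(s): ",
         paste(missing_st, collapse = ", "))
  }
  mets <- unique(unlist(lapply(model$stoichiometry, names)))
  unknown <- setdiff(mets, model$metabolites$id)
  if (length(unknown)) {
    stop("stoichiometry references undeclared metabolite(s): ",
         paste(unknown, collapse = ", "))
  }
  gpr_g <- unique(unlist(lapply(model$gpr, gpr_genes)))
  if (length(setdiff(gpr_g, model$genes))) {
    stop("GPR references genes missing from the model gene list")
  }
  invisible(model)
}

# Boundary classification. Biomass (nonzero objective) takes precedence, so
# a single-sided biomass equation (precursors -> nothing) is still "biomass";
# the single-sidedness rule then partitions the remaining reactions.
classify_boundary <- function(model) {
  vapply(seq_len(nrow(model$reactions)), function(i) {
    rid <- model$reactions$id[i]
    if (abs(model$reactions$objective_coefficient[i]) > 0) return("biomass")
    st <- model$stoichiometry[[rid]]
    st <- st[st != 0]
    one_sided <- length(st) > 0L && (all(st > 0) || all(st < 0))
    if (!one_sided) return("internal")
    bare <- sub("^R_", "", rid)
    if (startsWith(bare, "DM_")) "demand"
    else if (startsWith(bare, "SK_")) "sink"
    else "exchange"
  }, character(1))
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return Dense numeric matrix S with one row per metabolite and one column
#'   per reaction; `S[i, j]` is the signed coefficient of metabolite i in
#'   reaction j.
#' @export
stoich_matrix <- function(model) {
  m <- nrow(model$metabolites)
  n <- nrow(model$reactions)
  S <- matrix(0, m, n,
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    if (length(st)) S[names(st), rid] <- st
  }
  S
}

#' Human-readable reaction equation
#'
#' @param model a `metabolic_model`.
#' @param reaction_id one reaction id.
#' @return A string such as `"0.8 b_c + 0.2 p_c -->"`; reversible reactions
#'   (negative lower bound) use `<=>`.
#' @export
reaction_formula <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id)
  st <- model$stoichiometry[[reaction_id]]
  side <- function(v) {
    if (!length(v)) return("")
    paste(ifelse(abs(v) == 1, names(v), paste(abs(v), names(v))),
          collapse = " + ")
  }
  arrow <- if (model$reactions$lower_bound[i] < 0) "<=>" else "-->"
  paste(side(st[st < 0]), arrow, side(st[st > 0]))
}

# Returns model with reaction bounds replaced; overrides is a named list of
# c(lb, ub) (or a single value meaning both bounds).
apply_bounds <- function(model, overrides) {
  if (!length(overrides)) return(model)
  for (rid in names(overrides)) {
    i <- match(rid, model$reactions$id)
    if (is.na(i)) stop("bound override names unknown reaction: ", rid)
    v <- overrides[[rid]]
    if (length(v) == 1L) v <- c(v, v)
    if (v[1] > v[2]) stop("bound override with lb > ub for ", rid)
    model$reactions$lower_bound[i] <- v[1]
    model$reactions$upper_bound[i] <- v[2]
  }
  model
}

# Append a reaction; used by ensure_demand() and the toy generators.
add_reaction <- function(model, id, name, stoich, lb, ub,
                         objective_coefficient = 0, gpr = NULL) {
  if (id %in% model$reactions$id) stop("reaction id already present: ", id)
  model$reactions <- rbind(
    model$reactions,
    data.frame(id = id, name = name, lower_bound = lb, upper_bound = ub,
               objective_coefficient = objective_coefficient,
               boundary_kind = "internal", stringsAsFactors = FALSE))
  model$stoichiometry[[id]] <- stoich
  if (!is.null(gpr)) {
    model$gpr[[id]] <- gpr
    model$genes <- sort(unique(c(model$genes, gpr_genes(gpr))))
  }
  model$reactions$boundary_kind <- classify_boundary(model)
  validate_model(model)
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", x$id, "\n")
  cat("  metabolites:", nrow(x$metabolites),
      " reactions:", nrow(x$reactions),
      " genes:", length(x$genes), "\n")
  obj <- x$reactions$id[x$reactions$objective_coefficient != 0]
  cat("  objective:", if (length(obj)) paste(obj, collapse = ", ") else "<none>",
      "\n")
  invisible(x)
}
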