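# The UPA procedure: demand augmentation, flux-state comparison, yield
# re-verification, ranking, gene mapping and module grouping.

test_that("demand drains are reused or appended, idempotently", {
  model <- make_branch_model()
  aug <- ensure_demand(model, "p_c")
  expect_identical(aug$demand_id, "DM_p")
  expect_identical(nrow(aug$model$reactions), nrow(model$reactions))

  lin <- make_linear_model(3)
  aug2 <- ensure_demand(lin, "m2")
  expect_identical(aug2$demand_id, "DM_m2")
  i <- match("DM_m2", aug2$model$reactions$id)
  expect_equal(aug2$model$reactions$lower_bound[i], 0)
  expect_equal(aug2$model$reactions$upper_bound[i], 1000)
  expect_identical(aug2$model$reactions$boundary_kind[i], "demand")

  aug3 <- ensure_demand(aug2$model, "m2")
  expect_identical(aug3$demand_id, "DM_m2")
  expect_identical(aug3$model$reactions, aug2$model$reactions)
  expect_error(ensure_demand(model, "nope_c"), "unknown metabolite")
})

test_that("wild-type and maximum-yield states bracket the analysis", {
  model <- ensure_demand(make_branch_model(), "p_c")$model
  opts <- upa_options()
  wt <- wild_type_fluxes(model, "BIO", "DM_p", opts)
  expect_flux(wt, "RB", 8)
  expect_flux(wt, "RP", 2)
  expect_flux(wt, "BIO", 10)
  expect_flux(wt, "DM_p", 0)

  # halved uptake halves every wild-type flux (linear scaling)
  half <- apply_bounds(model, list(EX_glc = c(-5, 1000)))
  wt_half <- wild_type_fluxes(half, "BIO", "DM_p", opts)
  expect_equal(wt_half$fluxes[c("T1", "RB", "RP", "BIO")],
               wt$fluxes[c("T1", "RB", "RP", "BIO")] / 2, tolerance = 1e-8)

  # zero uptake: zero growth, all internal fluxes zero
  none <- apply_bounds(model, list(EX_glc = c(0, 0)))
  wt0 <- wild_type_fluxes(none, "BIO", "DM_p", opts)
  expect_equal(max(abs(wt0$fluxes)), 0, tolerance = 1e-8)

  opt <- optimum_fluxes(model, "DM_p", opts)
  expect_flux(opt, "DM_p", 10)
  expect_flux(opt, "RP", 10)
  expect_flux(opt, "BIO", 0)

  lin <- ensure_demand(make_linear_model(3), "m2")$model
  lopt <- optimum_fluxes(lin, "DM_m2", opts)
  expect_flux(lopt, "DM_m2", 10)
  expect_flux(lopt, "S2", 0)

  infeasible <- apply_bounds(model, list(BIO = c(100, 100)))
  expect_error(wild_type_fluxes(infeasible, "BIO", "DM_p", opts),
               "infeasible")
})

test_that("up-regulation detection excludes boundaries and sign reversals", {
  opts <- upa_options()
  model <- ensure_demand(make_branch_model(), "p_c")$model
  wt <- wild_type_fluxes(model, "BIO", "DM_p", opts)
  opt <- optimum_fluxes(model, "DM_p", opts)
  expect_identical(detect_upregulated(wt, opt, model, opts), "RP")

  lin <- ensure_demand(make_linear_model(3), "m2")$model
  lwt <- wild_type_fluxes(lin, "BIO", "DM_m2", opts)
  lopt <- optimum_fluxes(lin, "DM_m2", opts)
  expect_identical(detect_upregulated(lwt, lopt, lin, opts), character())

  # a newly activated branch (wild-type flux 0) is a candidate
  bonly <- ensure_demand(make_branch_model(biomass_stoichiometry = c(b_c = 1)),
                         "p_c")$model
  bwt <- wild_type_fluxes(bonly, "BIO", "DM_p", opts)
  expect_flux(bwt, "RP", 0)
  bopt <- optimum_fluxes(bonly, "DM_p", opts)
  expect_identical(detect_upregulated(bwt, bopt, bonly, opts), "RP")

  # a synthetic sign reversal is rewiring, not up-regulation
  wt2 <- wt; wt2$fluxes[["RP"]] <- -2
  expect_false("RP" %in% detect_upregulated(wt2, opt, model, opts))
})

test_that("yield re-verification scores direct contribution to production", {
  opts <- upa_options()
  model <- ensure_demand(make_branch_model(), "p_c")$model
  y <- verify_yield(model, "RP", 10, "BIO", "DM_p", opts)
  expect_equal(as.numeric(y), 10, tolerance = 1e-6)
  expect_false(attr(y, "infeasible"))

  # obligate degradation consumes any forced synthesis flux: yield 0
  deg <- ensure_demand(make_degradation_model(), "x_c")$model
  y0 <- verify_yield(deg, "SYN", 5, "BIO", "DM_x_c", opts)
  expect_equal(as.numeric(y0), 0, tolerance = 1e-4)

  # a clamp inconsistent with other constraints maps to yield 0, flagged
  forced <- apply_bounds(model, list(RB = c(8, 8)))
  yi <- verify_yield(forced, "RP", 10, "BIO", "DM_p", opts)
  expect_equal(as.numeric(yi), 0)
  expect_true(attr(yi, "infeasible"))

  expect_error(verify_yield(model, "EX_glc", 1, "BIO", "DM_p", opts),
               "internal")
})

test_that("ranking filters on yield, sorts by ratio, breaks ties by yield then id", {
  rec <- function(id, ratio, yield) {
    data.frame(reaction_id = id, reaction_name = id,
               genes = I(list(character())), formula = "",
               flux_wt = 1, flux_opt = ratio, ratio = ratio,
               yield_value = yield, stringsAsFactors = FALSE)
  }
  records <- rbind(rec("A", 5, 10), rec("B", Inf, 4), rec("C", 2, 7))
  ranked <- rank_candidates(records, upa_options())
  expect_identical(ranked$reaction_id, c("B", "A", "C"))
  expect_identical(ranked$rank, 1:3)

  ties <- rbind(rec("Z", 5, 3), rec("A", 5, 10), rec("M", 5, 3))
  ranked2 <- rank_candidates(ties, upa_options())
  expect_identical(ranked2$reaction_id, c("A", "M", "Z"))

  with_zero <- rbind(rec("A", 5, 10), rec("B", 7, 0))
  expect_identical(rank_candidates(with_zero, upa_options())$reaction_id, "A")
  # ratio at or below 1 is not an up-regulation
  with_flat <- rbind(rec("A", 5, 10), rec("B", 1, 10), rec("C", 0.5, 10))
  expect_identical(rank_candidates(with_flat, upa_options())$reaction_id, "A")
  expect_warning(rank_candidates(rec("B", 7, 0), upa_options()), "filtered")
})

test_that("gene sets flatten from GPRs per reaction", {
  model <- make_branch_model()
  expect_identical(genes_for(model, "RP"), c("gRP1", "gRP2", "gRP3"))
  expect_identical(genes_for(model, "RB"), c("gRB1", "gRB2"))
  expect_identical(genes_for(model, "EX_glc"), character())
  expect_error(genes_for(model, "NOPE"), "unknown")
})

test_that("module grouping splits on relative ratio gaps", {
  fake_result <- function(ratios) {
    cand <- data.frame(rank = seq_along(ratios),
                       reaction_id = paste0("R", seq_along(ratios)),
                       reaction_name = "", stringsAsFactors = FALSE)
    cand$genes <- I(rep(list(character()), length(ratios)))
    cand$formula <- ""
    cand$flux_wt <- 1; cand$flux_opt <- ratios; cand$ratio <- ratios
    cand$yield_value <- 1; cand$module <- NA_integer_
    structure(list(target_metabolite = "x", demand_id = "DM_x",
                   biomass_id = "BIO", theoretical_max_yield = 1,
                   candidates = cand, options = upa_options()),
              class = "upa_result")
  }
  g <- function(ratios, tol = 0.05) {
    group_modules(fake_result(ratios),
                  upa_options(module_rel_tol = tol))$candidates$module
  }
  expect_identical(g(c(10, 9.8, 4)), c(1L, 1L, 2L))
  expect_identical(g(7), 1L)
  expect_identical(g(c(Inf, Inf, 8, 7.9, 3)), c(1L, 1L, 2L, 2L, 3L))
  expect_identical(g(c(10, 9, 8.9, 2), tol = 0.2), c(1L, 1L, 1L, 2L))
})

test_that("the full analysis matches the enumeration oracle on the branch toy", {
  model <- make_branch_model()
  res <- run_upa(model, "p[c]")
  expect_identical(res$candidates$reaction_id, "RP")
  expect_identical(res$candidates$rank, 1L)
  expect_identical(res$candidates$module, 1L)

  # oracle route: wild type with the demand closed, then max production,
  # then lexicographic re-verification of the clamped candidate
  aug <- ensure_demand(model, "p_c")
  wt_o <- oracle_solve(close_demand(aug$model, aug$demand_id), "BIO")
  opt_o <- oracle_solve(aug$model, aug$demand_id)
  lex_o <- oracle_lex(aug$model, "BIO", aug$demand_id,
                      fixed = list(RP = unname(opt_o$fluxes[["RP"]])))
  expect_equal(res$candidates$flux_wt, unname(wt_o$fluxes[["RP"]]),
               tolerance = 1e-8)
  expect_equal(res$candidates$flux_opt, unname(opt_o$fluxes[["RP"]]),
               tolerance = 1e-8)
  expect_equal(res$candidates$ratio,
               abs(opt_o$fluxes[["RP"]]) / abs(wt_o$fluxes[["RP"]]),
               tolerance = 1e-8)
  expect_equal(res$candidates$yield_value, lex_o$secondary, tolerance = 1e-6)
  expect_equal(res$theoretical_max_yield, opt_o$objective_value,
               tolerance = 1e-8)
})

test_that("a newly activated pathway ranks first with infinite ratio", {
  res <- run_upa(make_branch_model(biomass_stoichiometry = c(b_c = 1)),
                 "p[c]")
  expect_identical(res$candidates$reaction_id[1], "RP")
  expect_true(is.infinite(res$candidates$ratio[1]))
  expect_identical(res$candidates$module[1], 1L)
  expect_gt(res$candidates$yield_value[1], 0)
})

test_that("targets needing only down-regulation give an empty result", {
  res <- suppressWarnings(run_upa(make_linear_model(3), "m2"))
  expect_identical(nrow(res$candidates), 0L)
  expect_gt(res$theoretical_max_yield, 0)
})

test_that("an obligately degraded target reproduces the known limitation", {
  deg <- make_degradation_model()
  res <- suppressWarnings(run_upa(deg, "x_c"))
  expect_identical(nrow(res$candidates), 0L)
  expect_equal(res$theoretical_max_yield, 0, tolerance = 1e-9)
  # the degradation-free target in the same model keeps the branch result
  res_p <- run_upa(deg, "p_c")
  plain <- run_upa(make_branch_model(), "p_c")
  expect_identical(res_p$candidates$reaction_id,
                   plain$candidates$reaction_id)
  expect_equal(res_p$candidates$ratio, plain$candidates$ratio)
  expect_equal(res_p$candidates$yield_value, plain$candidates$yield_value)
})

test_that("analysis is idempotent and invariant under bound rescaling", {
  model <- make_branch_model()
  a <- run_upa(model, "p[c]")
  b <- run_upa(model, "p[c]")
  expect_identical(a$candidates, b$candidates)

  for (k in c(0.5, 2)) {
    sc <- run_upa(scale_bounds(model, k), "p[c]")
    expect_identical(sc$candidates$reaction_id, a$candidates$reaction_id)
    expect_equal(sc$candidates$ratio, a$candidates$ratio, tolerance = 1e-8)
    expect_identical(sc$candidates$module, a$candidates$module)
    expect_equal(sc$candidates$yield_value, k * a$candidates$yield_value,
                 tolerance = 1e-6)
  }
})

test_that("biomass auto-selection demands a unique objective reaction", {
  model <- make_branch_model()
  none <- model
  none$reactions$objective_coefficient <- 0
  expect_error(run_upa(none, "p[c]"), "no objective")
  expect_identical(run_upa(none, "p[c]", biomass_id = "BIO")$biomass_id,
                   "BIO")
  several <- model
  several$reactions$objective_coefficient[
    match("RB", several$reactions$id)] <- 1
  expect_error(run_upa(several, "p[c]"), "several")
  expect_error(run_upa(model, "p[c]", biomass_id = "NOPE"),
               "unknown biomass")
})

test_that("pfba mode gives the same answer on non-degenerate toys", {
  res <- run_upa(make_branch_model(), "p[c]", upa_options(use_pfba = TRUE))
  expect_identical(res$candidates$reaction_id, "RP")
  expect_equal(res$candidates$ratio, 5, tolerance = 1e-6)
  expect_equal(res$candidates$yield_value, 10, tolerance = 1e-4)
})
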