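---
title: "Up-regulated pathway analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Up-regulated pathway analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upfinder)
```

## The problem

Overexpressing the right genes is the basic lever for overproducing a
metabolite in an engineered microbe. Given a genome-scale reconstruction, the
question is: which single reactions, if forced to carry more flux, *directly*
increase the achievable yield of a chosen product — as opposed to reactions
(glycolysis is the classic case) that are up-regulated en route to maximum
yield but whose sole overexpression changes nothing?

`upfinder` answers this with up-regulated pathway analysis (UPA), built
entirely on flux balance analysis (FBA): linear programs over the
steady-state constraint $Sv = 0$ and flux bounds $lb \le v \le ub$, with
fluxes in mmol·gDW⁻¹·h⁻¹.

## The procedure

For a target metabolite $m$:

1. **Demand augmentation.** An internal metabolite cannot be an FBA
   objective; it needs an irreversible drain. `ensure_demand()` reuses an
   existing demand/sink consuming exactly $m$ with bounds $[0, U]$, or
   appends `DM_<m>` with bounds $[0, 1000]$. This is the only construction
   consistent with steady state, and it is idempotent.
2. **Two flux states.** The *wild-type* state maximizes biomass with the
   demand closed (both bounds 0): `flux_wt` must describe the unengineered
   network, which does not secrete the product. The *maximum-yield* state
   maximizes the demand flux with the drain open; its optimum is the
   theoretical maximum yield and its fluxes are `flux_opt`.
3. **Detection.** An internal reaction is a candidate when
   $|flux_{opt}| > |flux_{wt}| + \varepsilon_{flux}$ and the two fluxes do
   not point in strictly opposite directions. A sign reversal is pathway
   rewiring, not something overexpression of the enzyme can accomplish, so
   it is excluded. Exchange, demand, sink and biomass reactions are never
   candidates — they are not gene targets.
4. **Re-verification.** Each candidate is clamped at its `flux_opt` (both
   bounds) in the wild-type network; biomass is maximized, then the product
   demand is maximized at the fixed growth optimum. The second optimum is
   the candidate's **Yield**. Candidates with Yield at zero are only
   indirectly related to production and are dropped. An infeasible clamp
   maps to Yield 0 (flagged) rather than aborting the run, so one
   pathological candidate cannot kill an analysis.
5. **Ranking and modules.** Survivors are sorted by
   $Ratio = |flux_{opt}|/|flux_{wt}|$, descending, with $Ratio = \infty$
   (wild-type flux below $\varepsilon_{flux}$: a newly activated pathway,
   maximally up-regulated) first; ties break by Yield then reaction id.
   Walking the ranked list, a new metabolic module starts when the relative
   gap between consecutive finite Ratios exceeds `module_rel_tol`; infinite
   Ratios form the leading module.

### Why a lexicographic yield

A single growth-objective solve leaves the product flux at the growth
optimum degenerate: any value between zero and the overflow capacity is
optimal for growth, and which one the solver reports is arbitrary. Yield is
therefore defined as the *maximum* product flux among growth-optimal
solutions — a lexicographic program (growth first, product second). The
second stage fixes growth to within $10^{-6}\max(1, |optimum|)$; exact
fixing is numerically brittle. A consequence is that yields below roughly
that tolerance times the network scale are not distinguishable from zero.

### The detection rule

One could call any reaction carrying flux in the maximum-yield state a
candidate. That admits reactions whose flux is unchanged (trivially "needed"
but not up-regulated) and reactions that reverse direction. We require a
strict magnitude increase with non-opposing signs — equivalently
$Ratio > 1$ — which matches the intent of identifying *up-regulated*
pathways and keeps the output interpretable as overexpression preference.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `eps_flux` | 1e-6 | magnitude below which a flux counts as zero; minimum detectable up-regulation (mmol·gDW⁻¹·h⁻¹) |
| `eps_yield` | 1e-6 | Yield filter threshold (same units) |
| `eps_rel` | 1e-6 | finite Ratios must exceed `1 + eps_rel` |
| `module_rel_tol` | 0.05 | relative Ratio gap opening a new module (5%) |
| `use_pfba` | FALSE | compute flux states parsimoniously (see below) |
| `bound_overrides` | — | growth/uptake conditions, `reaction -> c(lb, ub)` |

The three epsilons sit at the LP reporting precision; they are deliberately
far below any biologically meaningful flux. The module tolerance of 5% is a
presentation choice: modules are a reading aid, and the candidate list is
unaffected by it.

Plain FBA is the default everywhere; `use_pfba = TRUE` replaces the two flux
states with parsimonious solutions (minimum total absolute flux among
optima). Plain FBA optima are generally degenerate, and which vertex a
simplex implementation reports is implementation-dependent; candidate *sets*
are robust in our experience, but flux *values* of individual reactions can
differ between solvers. The parsimonious mode removes that freedom at the
cost of a second, larger LP per state.

## Numerical machinery

The LP backend is a dense two-phase bounded-variable primal simplex with
Bland's anti-cycling rule, behind a minimal solver contract (build problem,
solve, read primal values) so that any LP implementation could be
substituted. Feasibility tolerance is $10^{-9}$; non-finite bounds are
capped at $10^6$ and a solution pressing against such a cap is reported
unbounded. The backend is verified three ways: against frozen analytic
optima of the toy networks, against an exact vertex-enumeration oracle
(every full-rank column basis with the remaining fluxes pinned at either
bound), and against an independent external LP implementation on random
problems.

Degenerate inputs: a reaction fixed to a single value (lb = ub) is
eliminated by substitution before the solve; an infeasible wild type aborts
with a diagnostic; an unbounded maximum-yield problem (a model without
closed exchanges) aborts advising a bound review; a target whose theoretical
maximum yield is zero returns an empty result with a warning rather than an
error.

## What the synthetic networks emulate

The generators produce the smallest networks exhibiting each behaviour the
method must handle, with genome-scale conventions (bound magnitude 1000,
substrate uptake 10 mmol·gDW⁻¹·h⁻¹):

* `make_branch_model()` — a branch point splitting carbon between biomass
  and product: the canonical positive case. One candidate (the product
  branch, wild-type flux 2, optimum 10, Ratio 5, Yield 10 = the theoretical
  maximum).
* `make_linear_model(n)` — a single chain whose every synthesis flux is
  already maximal at the growth optimum: overproducing an interior
  intermediate needs only down-regulation downstream, so the correct answer
  is an empty candidate list.
* `make_degradation_model()` — the branch network plus an obligately coupled
  degradation pathway for a secondary product. Degradation that scales with
  production cannot be written as a fixed flux bound in an LP, so the
  coupling is stoichiometric: synthesis co-produces a coupling metabolite
  whose only consumer is the degradation reaction, which also consumes the
  product. Any forced synthesis flux is exactly cancelled; the target can
  never accumulate, and UPA correctly returns nothing — the method's known
  limitation for heavily degraded metabolites, reproduced in miniature.
* `make_parallel_model()` — two equivalent routes, the minimal degenerate
  LP, used to exercise the parsimonious mode.
* `random_toy_model(seed, topology)` — perturbs stoichiometric coefficients
  and bounds only, never topology, so the enumeration oracle stays cheap
  and the qualitative solution structure is preserved.

What passing these tests does *not* show: toy networks have no cofactor
balancing, no alternate optimal flux patterns at genome scale, no
compartmentalization, and GPRs of trivial size. Agreement with published
genome-scale candidate sets is a separate, network-dependent check that
requires the actual reconstructions (see the acceptance test), and plain-FBA
flux values at genome scale should be treated as one member of the optimal
set, not as unique predictions.

## Scope and limitations

* One candidate at a time: the method scores single-reaction
  overexpressions. It does not search for the best *combination* of
  targets, nor for knockout or down-regulation designs.
* Metabolites with obligate degradation or strictly growth-coupled
  consumption have no valid overexpression target and return empty results.
* Yield is reported as the demand flux in the model's flux units; it is a
  rate, and converting it to a mass yield requires the uptake stoichiometry
  of the chosen medium.
* Biomass selection must be unique: when a model declares several objective
  reactions (e.g. autotrophic vs. heterotrophic growth variants), the
  choice is mandatory (`biomass_id` / `--growth`), never silent.

## Problem sizes

All shipped analyses are intentionally small: toy networks of 5–10
reactions, 50 seeded random variants for the solver/oracle agreement and
property checks, and enumeration oracles up to 12 reactions. The entire
suite, including the exact oracles, runs in seconds on one core.
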