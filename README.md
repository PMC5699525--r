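# upfinder

Identification of gene **overexpression** targets for metabolic engineering
from genome-scale constraint-based models.

Overproducing a metabolite usually starts by overexpressing the genes of the
pathway that feeds it. `upfinder` finds those genes computationally: given an
SBML metabolic model and one target metabolite, it runs **up-regulated
pathway analysis (UPA)** and returns a ranked table of single-reaction
overexpression candidates, each annotated with its wild-type flux, its flux
at the theoretical maximum yield, its up-regulation Ratio, its re-verified
product Yield, its associated genes, and a Ratio-level metabolic module
label.

## Method

All analysis is flux balance analysis (FBA): linear programming over the
steady-state constraint *S v = 0* and flux bounds *lb ≤ v ≤ ub*, where *S*
is the stoichiometric matrix of the reconstruction.

1. **Flux comparison.** Solve the wild-type model (biomass objective, the
   target's demand drain closed) giving *flux_wt*, and the
   maximum-yield model (target demand as objective) giving *flux_opt*.
   Internal reactions with |*flux_opt*| > |*flux_wt*| (same flux direction)
   must be up-regulated to reach the theoretical maximum yield; they are the
   candidate set. Exchange, demand, sink and biomass reactions are never
   candidates.
2. **Re-verification.** Not every up-regulated reaction *drives*
   production. Each candidate is clamped at its *flux_opt* in the wild-type
   network; growth is maximized, and the product yield attainable at that
   growth optimum (a lexicographic second objective) is its **Yield**.
   Candidates with Yield = 0 — typically central-carbon reactions whose
   up-regulation alone accomplishes nothing — are dropped.
3. **Ranking.** Survivors are ranked by their up-regulation
   **Ratio = flux_opt / flux_wt** (magnitudes; `Inf` for newly activated
   reactions, which rank first). Higher Ratio means a stronger up-regulation
   demand, hence higher overexpression priority. Neighbouring Ratio levels
   are grouped into metabolic modules, which in practice coincide with
   functional pathway blocks.

The LP backend is a self-contained bounded-variable simplex behind a minimal
solver contract; a parsimonious-FBA mode (`use_pfba = TRUE`) is available to
remove the solver dependence of degenerate flux distributions.

## Worked example

A 6-reaction branched toy network: glucose uptake (10 mmol/gDW/h) feeds a
branch point A; branch RB makes the main biomass precursor, branch RP makes
product P, and biomass consumes 0.8 B + 0.2 P.

```r
library(upfinder)
model <- make_branch_model()
res <- run_upa(model, "p[c]")
print(res)
#> UPA result for target p_c (demand DM_p, biomass BIO)
#>   theoretical maximum yield: 10
#>  rank reaction_id          genes flux_wt flux_opt ratio yield_value module
#>     1          RP gRP1;gRP2;gRP3       2       10     5          10      1
```

Reading the row: at the growth optimum RP carries 2 flux units; to reach the
theoretical maximum product yield of 10 it must carry 10, a 5-fold
up-regulation. Clamping RP at 10 and re-simulating growth still delivers the
full yield of 10, so overexpressing RP's genes alone drives overproduction.
The transport reaction (10 → 10, unchanged) and all boundary reactions are
correctly absent.

The same analysis runs from a shell via the installed script:

```sh
upfinder run --model branch1.xml --target "p[c]" --method upa --out report.tsv
upfinder run --model branch1.xml --method fba   # growth_rate	10
```

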