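# fluxsum — metabolite-centric strain-design targets by flux-sum analysis

`fluxsum` identifies **metabolite** targets for microbial strain
improvement from a constraint-based (stoichiometric) metabolic model. It is
aimed at metabolic engineers and systems biologists who already use flux
balance analysis and want a metabolite-centric complement to
reaction-centric design methods: instead of asking which reactions to
knock out or modulate, it asks which metabolite's *turnover* should be
restricted or amplified.

## The quantity and the procedure

The turnover of an internal metabolite *i* at a steady-state flux vector
*v* is its **flux-sum**

Φ_i = ½ Σ_j |S_ij v_j|,

half the summed absolute rate of all reactions producing or consuming it
(at steady state, production = consumption = Φ_i). The workflow:

1. **Reference.** Solve FBA (max c'v subject to S v = 0,
   α_j ≤ v_j ≤ β_j), then re-optimize the target exchange in the
   goal-adverse sense with growth held at its optimum (lexicographic
   solve), and evaluate every Φ_i^WT on that solution.
2. **Range.** Compute each metabolite's feasible flux-sum range
   [Φ_i^min, Φ_i^max] by MILP — the absolute values are linearized with
   generation/consumption splits switched by exclusive big-M indicator
   binaries.
3. **Growth guarantee.** For k = 0, 0.1, …, 1 maximize biomass under one
   constraint: Φ_i ≤ Φ_i^min + k(Φ_i^WT − Φ_i^min) (attenuation) or
   Φ_i ≥ Φ_i^WT + k(Φ_i^max − Φ_i^WT) (intensification), giving B_ik.
4. **Guarantee on production.** With biomass ≥ B_ik, optimize the target
   exchange adversarially; if the guaranteed production beats the
   wild-type guarantee, the metabolite is an engineering target.

Everything runs on a built-in bounded-variable simplex plus
branch-and-bound — no external solver required. Models load from the
community JSON dialect or SBML Level 3 (flux-bounds subset); toy
fermentation networks are generated programmatically.

## Worked example

A reduced anaerobic mixed-acid fermentation network (glucose in through a
PEP-consuming phosphotransferase step; succinate, ethanol, acetate,
formate, lactate out; biomass = ATP regeneration), scanned for metabolites
whose flux-sum perturbation forces succinate secretion:

```r
library(fluxsum)
m <- mixed_acid_model()
scan <- fsa_scan(m, "EX_succ", goal = "maximize")
scan
#> <fsa_scan> target=EX_succ goal=maximize
#>   wild type: growth=30, guaranteed production=0
#>   264 scan points, 5 target(s)
#> # A tibble: 5 × 5
#>   metabolite direction       best_k best_production growth_at_best
#>   <chr>      <chr>            <dbl>           <dbl>          <dbl>
#> 1 fum        intensification    1             10              20
#> 2 mal        intensification    1             10              20
#> 3 oaa        intensification    1             10              20
#> 4 pyr        attenuation        0.5           10.00           20.0
#> 5 succ       intensification    1             10              20
```

At the wild-type optimum the network secretes acetate and ethanol and
*guarantees* no succinate at all (worst-case production 0 at growth 30).
Attenuating the pyruvate flux-sum redirects the phosphoenolpyruvate branch
point toward fumarate reductase:

```r
production_profile(scan, "pyr", "attenuation")
#> # A tibble: 11 × 3
#>        k growth production
#>    <dbl>  <dbl>      <dbl>
#>  1   0     0          0
#>  2   0.1   4.00       2.00
#>  ...
#>  6   0.5  20.0       10.00
#>  ...
#> 11   1    30.0        0
```

The profile is triangular: moderate attenuation (k = 0.5) guarantees 10
units of succinate at two-thirds of the wild-type growth, while excessive
attenuation (k → 0) throttles the PEP-coupled uptake itself and the
guarantee collapses. The direct succinate-path metabolites
(oaa/mal/fum/succ intensification) appear as the complementary, trivially
forcing targets. `autoplot(scan)` draws the profiles;
`tidy(scan)`/`glance(scan)` give the point table and a one-row summary.

A command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("exec/fsa", package="fluxsum"))') \
  scan --model model.json --target EX_succ --goal maximize --out out/
```

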