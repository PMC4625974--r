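---
title: "Flux-sum analysis: model, machinery and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-sum analysis: model, machinery and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxsum)
```

## The problem

Classical in-silico strain design is reaction-centric: it searches over
knockouts or flux modulations of individual reactions, and multi-reaction
interventions quickly hit combinatorial explosion. A metabolite-centric
alternative asks a different question: what happens if we restrict or force
the *turnover* of one metabolite — the total rate at which the network
produces (equivalently, at steady state, consumes) it? Because a single
metabolite commonly touches many reactions, one turnover constraint stands
in for a whole family of coordinated reaction perturbations.

The turnover measure is the **flux-sum**. For an internal metabolite $i$
with stoichiometric coefficients $S_{ij}$ and reaction fluxes $v_j$,

$$\Phi_i \;=\; \tfrac{1}{2}\sum_j |S_{ij}\,v_j|,$$

half the summed absolute incident rate. At steady state
($\sum_j S_{ij} v_j = 0$ for every internal $i$) generation and consumption
are equal, so $\Phi_i$ equals both.

`fluxsum` implements the full target-identification workflow on top of flux
balance analysis (FBA): given a stoichiometric model, a biomass reaction
and a target exchange reaction, it finds metabolites whose flux-sum
**attenuation** (capping $\Phi_i$ below its wild-type value) or
**intensification** (forcing it above) *guarantees* an improvement in the
target secretion while maintaining a stated growth level.

## The optimization machinery

FBA is the LP
$\max c^\top v$ subject to $S v = 0$, $\alpha_j \le v_j \le \beta_j$.
The flux-sum is nonlinear in $v$, so constraints on it are linearized with
a generation/consumption split per incident reaction:

$$S_{ij} v_j = g_{ij}^+ - g_{ij}^-,\qquad
  g_{ij}^\pm \ge 0,\qquad
  g_{ij}^+ \le I_{ij} M,\quad g_{ij}^- \le (1 - I_{ij}) M,\quad
  I_{ij}\in\{0,1\},$$

so that exactly one side is active and
$\Phi_i = \tfrac12\sum_j (g_{ij}^+ + g_{ij}^-)$ becomes linear. $M$ is a
big-M flux cap (default 1000 mmol/gDCW-hr). Two reductions keep the
mixed-integer problems small, both exactly equivalence-preserving:

* split variables are instantiated only for reactions incident to the
  instrumented metabolite ($S_{ij} \ne 0$) — other reactions contribute
  nothing to $\Phi_i$;
* reactions whose bounds confine the flux to one sign need no binaries:
  the split is forced and $|S_{ij} v_j|$ is itself linear. This reduction
  can be disabled (`solve_config(reduce_forced_splits = FALSE)`), which the
  test-suite uses to exercise the full indicator machinery against a
  binary-free LP formulation on all-irreversible networks.

The workflow has four steps:

1. **Reference state.** Maximize biomass; then, holding growth at that
   optimum, re-optimize the target exchange in the *goal-adverse* sense
   (minimize it when the goal is to maximize production). The wild-type
   flux-sums $\Phi_i^{WT}$ are evaluated on this second, lexicographic
   solution. FBA optima are typically degenerate, and $\Phi_i^{WT}$ is not
   well defined at "the" FBA optimum; the lexicographic convention makes
   the reference reproducible and conservative, and is echoed in every
   report (`phi_wt_convention` metadata).
2. **Extrema.** $\Phi_i^{\min}$ and $\Phi_i^{\max}$ by MILP under mass
   balance and bounds only — deliberately without a growth constraint, so
   the range brackets everything the stoichiometry allows.
3. **Perturbed growth.** For each level $k \in \{0, 0.1, \dots, 1\}$,
   maximize biomass under a single interpolated constraint:
   attenuation $\Phi_i \le \Phi_i^{\min} + k(\Phi_i^{WT}-\Phi_i^{\min})$,
   or intensification
   $\Phi_i \ge \Phi_i^{WT} + k(\Phi_i^{\max}-\Phi_i^{WT})$. The optimum is
   the growth guarantee $B_{ik}$. The constraint sets are nested in $k$,
   so $B_{ik}$ is monotone — a property the tests assert.
4. **Worst-case production.** With growth floored at $B_{ik}$, optimize
   the target exchange in the goal-adverse sense. The result is the
   *guaranteed* production under the perturbation; a metabolite is a
   target when some scan point beats the wild-type guarantee.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `big_M` | 1000 mmol/gDCW-hr | cap on split variables; validated against the largest finite bound and auto-raised (warning) to 10x that bound if too small; a post-solve assert rejects any solution touching the cap |
| `lp_tolerance` | 1e-9 | simplex feasibility/optimality tolerance |
| `integer_tolerance` | 1e-6 | binary integrality tolerance; also the degeneracy cutoff for flux-sum ranges |
| `lex_slack_rel`, `lex_slack_abs` | 1e-9, 1e-9 | the primary optimum of a lexicographic solve is held as an inequality with slack `max(abs, rel * |opt|)` — an exact equality re-solve is numerically brittle |
| `k_grid` | 0, 0.1, ..., 1 | perturbation levels between the wild-type value and the relevant extremum |
| `improvement_rel`, `improvement_abs` | 1e-3, 1e-6 | classification threshold: a point must beat the wild-type guarantee by `max(abs, rel * |wt|)`; this suppresses solver noise without hiding genuine sub-unit improvements |
| `exclude` | empty | optional currency-metabolite exclusion list; off by default because cofactor-adjacent metabolites (quinones, redox carriers) are legitimate and interesting targets |

Degenerate ranges ($\Phi^{WT} \approx \Phi^{\min}$ for attenuation,
$\Phi^{\max} \approx \Phi^{WT}$ for intensification, within
`integer_tolerance`) are skipped with a reason code instead of producing a
column of identical points: the interpolated constraint would be vacuous or
infeasible-by-rounding. Infeasible growth solves record their status —
never growth 0, which would silently corrupt the monotonicity property. If
the wild-type growth itself is 0 the scan still runs, flagged
`non_growing`.

## The solver

No LP or MILP library is assumed: the package carries a dense two-phase
bounded-variable revised simplex (`solve_lp()`) and a depth-first
branch-and-bound layer over the indicator binaries (`solve_milp()`). The
problems this package generates are small — tens of rows, tens of columns,
rarely more than a handful of binaries after the forced-split reduction —
so the basis inverse is recomputed from scratch each iteration, trading
speed for robustness, and the entering rule falls back from Dantzig to
Bland after 2000 iterations to guarantee termination under degeneracy.
The test-suite cross-checks the simplex against an independent external
solver (HiGHS, via scipy) on randomized problems, and the branch-and-bound
against exhaustively verifiable integer programs. Unboundedness is
reported as a status, never clamped; big-M capping exists only inside the
flux-sum machinery.

## Toy networks and what they do (not) show

`two_branch_model()` is the analytic anchor: a fixed uptake of 10 splits
over two parallel branches, one feeding biomass, one feeding the product.
Every workflow quantity has a closed form — attenuating the turnover of
the branch-point metabolite C to fraction $k$ of wild type forces product
secretion of exactly $10(1-k)$ at growth $10k$. A subtlety worth noting:
on this network the four constraints "cap C", "cap F", "force B", "force
E" pin the *same* branch split, so the scan correctly reports four
equivalent targets; the C-attenuation profile is the canonical one.

`mixed_acid_model()` is a reduced anaerobic fermentation network — PTS
uptake consuming phosphoenolpyruvate, a lumped glycolysis, the PEP branch
point toward succinate (via oxaloacetate/malate/fumarate and fumarate
reductase) or pyruvate, the pyruvate fates (lactate, formate+acetyl-CoA,
acetyl-CoA+NADH), and the acetyl-CoA fates (acetate with ATP gain, ethanol
with NADH consumption), with NAD/NADH and ATP/ADP balanced internally and
biomass modeled as ATP regeneration. One deliberate deviation from
unit stoichiometry: lumped glycolysis yields **two** PEP (with 2 NADH and
1 ATP) per glucose 6-phosphate, because the PTS step consumes one PEP per
glucose — with unit coefficients the network could never gain PEP and
would be dead. All coefficients remain small integers, so analytic oracles
stay exact. The network reproduces, at toy scale, two signature behaviors
of the genome-scale analysis: the triangular succinate-vs-$k$ profile
under pyruvate flux-sum attenuation (moderate attenuation redirects the
PEP node toward fumarate reductase; excessive attenuation throttles
PTS-coupled uptake and ATP regeneration), and the weak ethanol improvement
from inserting pyruvate decarboxylase, whose presence only enlarges the
feasible space under acetaldehyde flux-sum intensification.

What passing these tests does **not** show: toy networks have no
gene–protein–reaction structure, no maintenance ATP drain, no uptake
kinetics and unit-scale stoichiometry, so quantitative values do not
transfer to genome-scale models; only the workflow logic, the linearization
correctness, and the qualitative response shapes are validated. The
genome-scale readers (community JSON dialect, SBML Level 3 with the
flux-bounds extension) accept real models unmodified, but genome-scale
scans are MILP-heavy and belong on a dedicated solver budget.

`random_irreversible_model()` generates layered all-irreversible networks
(capped uptake, chain backbone, random shortcuts, spill and target
exchanges). On such networks $|S_{ij} v_j| = |S_{ij}| v_j$, so every MILP
quantity has an independent binary-free LP formulation; the acceptance
checks run both routes (with the forced-split reduction disabled, so the
indicator machinery is genuinely exercised) on 20 networks per run and
compare all quantities to 1e-6. Problem sizes throughout the test-suite
and acceptance script — networks of 4–8 metabolites, full 0.1 grids on the
mixed-acid network, 100 random feasible points for the extrema property —
were chosen so the whole suite completes in a couple of minutes on one
core while still covering every code path.

## Worked example

```{r two-branch}
m <- two_branch_model()
scan <- fsa_scan(m, "EX_E", goal = "maximize")
scan$targets
production_profile(scan, "C", "attenuation")
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(scan)
```

## Known limitations

* Worst-case production is evaluated one metabolite at a time; combined
  multi-metabolite flux-sum constraints are not explored.
* The wild-type production reference is the worst case at maximum growth.
  The best case is available by flipping the final objective sense, but
  classification always uses the conservative guarantee.
* The branch-and-bound layer is exact but unsophisticated (no cuts, no
  warm starts); genome-scale scans with many reversible incident reactions
  will be slow.
* The SBML reader covers the flux-balance-constraints subset only: species,
  reactions, stoichiometry, parameter-referenced bounds, objectives.
  Kinetic-law-encoded bounds are rejected with an explicit error.
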