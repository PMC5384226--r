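---
title: "Unsteady-state flux balance analysis: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsteady-state flux balance analysis: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ufbar)
```

## The problem

Flux balance analysis (FBA) treats a metabolic network at steady state: with
stoichiometric matrix $S$ (metabolites $\times$ reactions) and flux vector
$v$, it imposes $S v = 0$ together with flux bounds, and interrogates the
resulting polytope. Dynamic systems — stored red blood cells, stored
platelets, batch fermentations — violate the steady-state premise: large
intracellular metabolite pools fill or drain over days, and those pools can
dominate pathway flux. Time-course absolute-quantitative metabolomics makes
the pool dynamics observable.

Unsteady-state FBA (uFBA) replaces the zero right-hand side for every
*measured, significantly changing* metabolite with the measured rate of
change: the mass balance becomes

$$ b_1 \le S v \le b_2 $$

componentwise, where $[b_1, b_2]$ is the 95% confidence interval of the
metabolite's concentration slope and is $[0, 0]$ for every unmeasured or
non-significant metabolite. The model is treated as a *closed system*: all
exchange reactions are removed, and a metabolite may enter or leave only if
its change was measured or if the relaxation algorithm (below) requires it.

This package implements the full workflow on that formalism: data
preparation, discretization of the time course into linearized metabolic
states, rate estimation, model construction, the metabolite-node relaxation
algorithm, and the comparison machinery (flux variability analysis, uniform
flux sampling, sampled-state comparison statistics, single-gene
essentiality).

## Workflow and design choices

### Imputation

Missing concentrations are filled by weighted k-nearest-neighbour imputation
(`impute_missing()`, default $k = 5$): the neighbours of a metabolite profile
are the other metabolite profiles, nearness is root-mean-square Euclidean
distance over co-observed coordinates, and the imputed value is the
inverse-distance-weighted average of the $k$ nearest profiles observed at
that coordinate. Non-missing values are never touched, so the operation is
idempotent.

### Discretization into metabolic states

Metabolite trajectories are rarely linear over a whole experiment, but are
close to linear within phases. `discretize_states()` makes the phase
structure explicit:

1. replicate-average each metabolite per time point;
2. standardize each metabolite to Z-scores across time (zero-variance
   metabolites are dropped from this step but kept for regression);
3. take the first principal component of the time-point $\times$ metabolite
   Z-score matrix;
4. segment the PC1 score trajectory by exhaustive dynamic-programming
   segmented regression: contiguous windows of at least 3 time points
   minimizing total within-segment SSE.

How a PCA "objectively determines" the intervals is genuinely open; the
dynamic program with an explicit selection rule is this package's choice.
When `n_states` is supplied the segment count is fixed; otherwise the
smallest $k$ capturing 95% of the achievable SSE reduction is used (an elbow
rule). A two-point window would give a zero-width confidence interval and
spurious significance, hence the three-point floor.

### Rate estimation

Within each window, `estimate_rates()` fits ordinary least squares of
concentration against time per metabolite, pooling replicate measurements as
independent observations so that the confidence interval reflects replicate
noise (the alternative — averaging replicates first — discards exactly the
variance the interval is meant to capture). The two-sided $(1-\alpha)$
interval comes from the t distribution; a metabolite is *significant* iff
the interval excludes zero, otherwise it is deemed at steady state. All
internal rates are per hour; day-denominated inputs are converted at ingest
(`read_timecourse_csv(time_units = "days")`). Unresolved assay pools
(3PG/2PG, pentoses, Leu/Ile and the like) are split only by an explicit
user-supplied ratio table (`split_pooled()`); no physiological ratios are
hard-coded.

### Model construction

`build_ufba_model()` removes all exchange reactions and adds, for each
significant rate, a single-metabolite *accumulation pseudo-reaction*
`{met: -1}` with flux bounds $[b_1, b_2]$ — positive flux accumulates the
metabolite out of the network. This keeps the system in standard
$S v = 0$ form for every downstream LP, MILP, QP and sampler; the
accumulation flux *is* the $b$ of the unsteady mass balance, and the full
confidence interval (not the point slope) becomes the bound pair.
Extracellular and intracellular measurements are treated identically, and
non-significant measured metabolites are treated exactly as unmeasured
ones. Growth-rate bounds are applied to the biomass (objective) reaction
when supplied; declared metabolite reserves (glycogen-store style) receive
reversible sinks.

`build_fba_control()` builds the steady-state control the method is
compared against: only extracellular significant rates are integrated, all
intracellular metabolites are balanced, and every unmeasured extracellular
metabolite receives a free efflux `[0, 1000]` — the standard FBA practice
of letting unmeasured products leave the system, which is precisely the
practice whose failure modes (e.g. free amino-acid efflux absorbing redox
imbalance) the closed formulation avoids.

A note on degrees of freedom: a fully closed mass-conserving $S$ has a rank
deficiency of one (its rows sum to zero), so the *first* accumulation
column restores full row rank and adds no degree of freedom; each further
accumulation or retained sink on a connected network adds one. The package
exposes `model_dof()` and the tests assert this algebra.

### Metabolite-node relaxation

Measurements never cover the whole network, so the closed model is usually
infeasible: some unmeasured metabolites must also deviate from steady
state. For every unmeasured metabolite the algorithm installs an "up" sink
(accumulation, `{met: -1}`, flux $\ge 0$) and a "down" sink (depletion,
`{met: +1}`, flux $\ge 0$), then chooses parsimoniously which sinks to
retain. Five formulations are implemented (`case` 1–5):

| case | class | objective |
|------|-------|-----------|
| 1 | MILP | number of relaxed nodes $\sum_j y_j$ (default) |
| 2 | LP   | summed sink flux $\sum_j (u_j + w_j)$ |
| 3 | LP   | case 2 $+ \sum_i \lvert v_i \rvert$ over intracellular reactions |
| 4 | QP   | $\sum_j (u_j^2 + w_j^2)$ |
| 5 | QP   | case 4 $+ \sum_i v_i^2$ |

Case 1 is the default because minimizing the *count* of relaxed nodes
minimizes the growth in degrees of freedom and was found the most accurate
selection rule in benchmarking against independent qualitative data; it is
also the most conservative (its support is never larger than case 2's).

Implementation details the formulations leave open, and the choices made
here:

* **Indicator coupling.** The MILP needs $d_j \le M y_j$; $M$ defaults to
  the global flux-bound proxy (1000). A node counts as relaxed iff its sink
  flux exceeds $10^{-9}$.
* **Alternative optima.** The chosen formulation is re-solved under integer
  cuts ($\sum_{j \in Y} y_j - \sum_{j \notin Y} y_j \le |Y| - 1$ for each
  previously returned support $Y$) for up to `iterations` rounds (study
  default 100), stopping early when the cut-augmented problem becomes
  infeasible or the objective degrades beyond the first optimum. Integer
  cuts are natural only for binaries; for the LP cases 2–3 auxiliary
  indicators ($\varepsilon y_j \le u_j + w_j \le M y_j$) are introduced
  solely to express the cuts. Cases 4–5 are strictly convex in the sink
  fluxes and return a single support.
* **Per-iteration termination.** Relative MILP gap $10^{-6}$ or 45 s,
  both configurable.
* **Final selection.** Supports are tallied across iterations and one final
  node-selection MILP runs with per-node cost $c_j = 1 - f_j + \varepsilon$,
  $f_j$ the tally frequency and $\varepsilon = 10^{-3}$, so cardinality
  still dominates and frequency guides within equal cardinality. The exact
  weighting is not prescribed anywhere; this linear form is the package's
  documented choice. With `exo_preference = TRUE` extracellular node costs
  are additionally halved, mirroring the common practice of adjusting
  extracellular exchanges first. The retained nodes' sinks (both
  directions) stay; every other sink is deleted. Reported directions come
  from the sink-flux-minimizing point, since an arbitrary MILP vertex can
  carry futile up+down circulation.
* **Magnitudes.** `fix_relaxation_magnitudes()` minimizes the total
  retained-sink flux and caps each sink at `scale` times its minimum
  (default 1.5$\times$). A 1$\times$ cap pins the model to the minimizing
  vertex and visibly shifts sampled flux states, while 1.5/5/10$\times$
  caps give near-identical states — the package's scaling-sensitivity
  analysis reproduces this plateau on the pool-depletion fixture.

The `pool_depletion` fixture is analyzed with `exo_preference = TRUE`: the
unmeasured product chain (O → L → secreted L) lets the excess flux surface
at any of three nodes, a genuine tie in cardinality, and the extracellular
preference resolves it toward the secreted product exactly as in the
stored-cell use case.

### Linear, integer and quadratic solving

No LP or MILP solver library ships with this package's dependency set, so
the numerical layer is self-contained: a dense two-phase bounded-variable
primal simplex (`lp_solve()`, Dantzig pricing with a Bland anti-cycling
fallback), an LP-based best-bound branch-and-bound for the binary
indicators (`milp_solve()`), and `quadprog` for the strictly convex QP
cases. All polytopes the package poses are bounded (the $\pm 1000$ proxy
stands in for unbounded directions), which the simplex exploits. The
solvers are validated in the test suite against frozen reference optima
computed with an independent solver and against brute-force enumeration.
These routines are sized for the package's problem scale — tens of
reactions, at most a dozen binary indicators; genome-scale work should link
a production solver.

### Flux sampling

`sample_fluxes()` implements artificial-centering hit-and-run: warmup
points are the FVA optima (two per reaction), each step draws a direction
from a stored point minus the running center — a difference of feasible
points, hence in the null space of $S$ — and moves uniformly within the box
limits. Two numerical safeguards matter in practice: the direction is
re-projected onto the null space *before* normalization (normalizing a
nearly-zero difference otherwise amplifies round-off out of the constraint
set catastrophically), and the current point is re-projected every 50
steps. The mixed-fraction diagnostic is the fraction of (sample, reaction)
pairs that remain on the same side of the per-reaction median between the
first and second half of the chain — 1 when unmixed, 0.5 at perfect
mixing; sampling restarts with doubled thinning until it falls below the
0.54 threshold. Every stored sample is checked against $S v = 0$ and the
bounds at $10^{-6}$; a violation is an error, not a warning.

### Comparing flux states

`compare_flux_states()` restricts to reactions present in both models and
in no type-3 loop of either (`exclude_loop_reactions()` closes every
boundary, accumulation and sink reaction and maximizes/minimizes each
remaining reaction; anything that can still carry flux is an internal,
thermodynamically infeasible cycle). Two statistics are computed, both of
which need an operational definition the literature leaves loose:

* **Overlap** of the two per-reaction sampled distributions: shared
  equal-width binning (Freedman–Diaconis on the pooled samples, at least 20
  bins), overlap $= \sum_b \min(p_b, q_b)$; a reaction differs
  significantly when overlap $< 0.05$.
* **Spearman distribution**: sample vectors of the two sets are paired
  after independent shuffles, one pairing per stored sample, and the rank
  correlation of each pair over the shared reactions is recorded. Pairing
  by shuffle makes the self-comparison (one model sampled twice) the
  correct null reference for the cross comparison.

### Gene essentiality

`gene_essentiality()` evaluates each reaction's boolean gene rule
(`and`/`or`/parentheses) with one gene knocked out, closes reactions whose
rule is false, and re-optimizes growth; a gene is essential when the
optimum drops below 1% of the reference growth rate. For unsteady models
the knockout protocol first makes the zero flux vector admissible —
accumulation intervals excluding 0 are widened to include it (a *forced*
depletion becomes an *allowed* depletion) — and opens efflux out of the
system for extracellular metabolites. It is exactly this protocol that
reproduces the cofactor-rescue phenomenon: a biosynthesis knockout is
lethal under the steady-state control but non-essential in the unsteady
model whose measured cofactor pool may drain.

## The synthetic-data generator

`make_toy_network()` / `make_scenario()` / `simulate_timecourse()` provide
the package's study conditions. Concentrations follow the workflow's own
linearization assumption exactly — $C(t) = C_0 + (S v_{\text{state}})(t -
t_{\text{start}})$ accumulated over states — then multiplicative Gaussian
replicate noise (SD proportional to concentration, the usual metabolomics
error structure), then missingness and the measured-metabolite mask.
Defaults are 5 replicates, 10 time points per state, 10 h per state and 5%
relative noise: a realistic mid-size time-course design. Initial
concentrations are set high enough that no trajectory goes negative.

The named topologies encode the workflow's characteristic situations: a
`chain` and a `branched` network (the latter with one interior degree of
freedom, used as the steady-state negative control with full extracellular
coverage), `pool_depletion` (a large measured intracellular pool feeding
secreted products through a reversible dehydrogenase, where the
steady-state control provably reverses the dehydrogenase direction; it
also carries four independently measured two-metabolite calibration paths
whose flux values are placed between the free means and the corner values
of the main pathway fluxes, so that constraint tightening is visible in
rank statistics), `cofactor_rescue` (the essentiality motif, with an
isozyme pair on the uptake step), and `twin_pathway` (two symmetric routes,
the alternative-optima motif). `make_random_instance()` generates random
acyclic networks with random measured subsets for oracle-equivalence
testing, and `relaxation_oracle()` is the independent brute force:
enumerate unmeasured-metabolite subsets by cardinality and test LP
feasibility.

What the generator does *not* emulate: enzyme kinetics and saturating
dynamics (an exponential-decay trajectory variant exists only as noise-free
piecewise-linear segments here), measurement-platform batch effects,
metabolite identification errors, and genome-scale network structure.
Passing tests therefore demonstrate correctness of the machinery on data
matching the method's own assumptions, not robustness to every failure
mode of real metabolomics.

## Numerical choices and degenerate inputs

* Unbounded flux directions are encoded as $\pm 1000$ (configurable at the
  reaction level); every optimization problem is therefore bounded.
* Simplex pivot tolerance $10^{-9}$; phase-1 feasibility at $10^{-7}$
  scaled by the right-hand side; branch-and-bound integrality at
  $10^{-6}$.
* A relaxation sink with minimized flux below $10^{-9}$ is treated as zero
  and its bound closes.
* Ties in the segmented-regression dynamic program (a time point lying
  exactly on two segment lines) are broken toward the earlier breakpoint;
  such ties are degenerate and translation of the time axis can flip them.
* Zero-variance metabolites are excluded from the PCA but retained for
  regression; a dataset with no varying metabolite yields a single state.
* A fully determined flux polytope (a single point) is sampled as that
  point with the mixed fraction reported as converged.
* An infeasible FBA solve is a *status*, not an exception; an infeasible
  relaxation base problem (even with all sinks open) is the error
  "data inconsistent with stoichiometry".

## Problem sizes in the test suite

The suite exercises toy networks of 3–20 reactions, 50 random
oracle-equivalence instances (up to 12 unmeasured metabolites each,
checked against exhaustive subset search), 1000 simulated regression
windows for confidence-interval coverage, and sampled chains of 300–1000
points per model. A full run takes well under a minute of solver time on
one core; the acceptance script re-runs the headline analyses end to end
in a few seconds.

## Limitations

* The solvers are pure R and sized for toy-to-small networks; genome-scale
  models need an external LP/MILP backend.
* SBML support covers the constraint-based subset (species, compartments,
  stoichiometry, flux-bound parameters, objective, gene associations);
  kinetic laws, events and unit algebra are out of scope.
* Cell death/lysis is not modeled; measured rates are attributed entirely
  to metabolism.
* The relaxation decides *which* nodes deviate, not whether the deviation
  is thermodynamically sensible; directions are constrained only by
  stoichiometry.
* Organelle-resolved concentrations are generally unavailable; compartment
  assignment of measurements is a user decision (with a default-to-cytosol
  convention).
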