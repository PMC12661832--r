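---
title: "Simulating cecal communities and quantifying cross-feeding with cecosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating cecal communities and quantifying cross-feeding with cecosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`cecosim` simulates a cecal microbial community as a collection of
individual bacteria on a two-dimensional grid, each carrying a
genome-scale metabolic model (GEM) of its species, and quantifies the
cross-feeding structure that emerges from their exchange fluxes. The
simulation couples three ingredients:

1. **Flux balance analysis (FBA).** Each GEM is a stoichiometric matrix
   $S$ with flux bounds; at every hour each individual solves
   $\max\, v_{\mathrm{biomass}}$ subject to $Sv = 0$,
   $l \le v \le u$, where exchange lower bounds are tightened to the
   nutrient amounts the individual can actually claim from its
   environment. Because the optimal flux vector of an LP is generally not
   unique, a second stage minimises $\sum_i |v_i|$ at the fixed growth
   optimum (parsimonious FBA). Exchange fluxes are the raw data of every
   downstream statistic, so they must not depend on solver internals;
   parsimony pins them to a canonical optimum.
2. **An individual-based arena.** Individuals occupy grid cells (one per
   cell), take one random-walk step per hour, grow by the Euler update
   $b \leftarrow b(1 + \mu\,\Delta t)$, and divide when they reach twice
   the seeding biomass, placing the daughter in a free neighbouring cell.
3. **Cecal hydraulics.** Every hour a diet influx is added and the
   metabolite pools are fully mixed; every fourth hour 25% of grid cells
   are cleared, removing their individuals and the corresponding share of
   the mixed pools — the periodic emptying of the cecum. Oxygen is capped
   at an ambient-derived trace value (1e-8 mM) and pH 7 is carried as
   metadata: the arena is effectively anaerobic and pH has no kinetic
   effect.

The linear programs are solved by a dense two-phase simplex written for
this package (no LP backend is required); Bland's pivoting rule
guarantees termination on the degenerate bases that flux problems
routinely produce. The test suite cross-checks every fixture optimum
against an independent brute-force enumeration of basic feasible
solutions.

### Mixing: why pools are fully stirred

The influx is "evenly distributed" across the grid each hour, and the
emptied fraction removes a matching share of the pools. Full mixing makes
the mass balance exactly auditable: the per-iteration ledger
(`$ledger`) closes to floating-point precision, which the tests assert at
a relative 1e-9. A per-cell diffusion mode would blur this guarantee
while changing little at the 1-hour timestep; it is deliberately not the
default.

### Units and scales

| parameter | default | meaning |
|---|---|---|
| grid | 100 × 100 cells | one individual per cell |
| timestep | 1 h | one FBA solve per individual per step |
| iterations | 16 | one feeding cycle |
| replicates | 5 | independent seeded repetitions |
| emptying | 25% every 4 h | cells cleared, pools reduced in proportion |
| `ref_biomass` | 1e-12 gDW | seeding biomass; division at 2× |
| `vmax` | 10 mmol/gDW/h | default uptake cap |
| `cell_volume` | 1e-12 L | converts diet mM into pool mmol |
| O2 | 1e-8 mM | fixed uptake cap; pH 7 metadata only |

`cell_volume` sets the trophic scale: with the default diet it lets a
community of a few hundred to a few thousand individuals deplete the
hourly dose within a few hours, so that competition and cross-feeding —
not unlimited substrate — shape growth.

Community sizes are derived from total 16S qPCR abundances: the natural
log of each sample's total is rescaled linearly from the cohort's
[ln min, ln max] onto 1000–5000 individuals, and every species receives
at least 5 individuals. The defaults span the measured cohort spread
(1.62e9–3.02e11 copies/g), and the synthetic generator draws totals
log-uniformly over the same range so the rescaling path is exercised.

### Uptake rationing

Within an hour, individuals act in seeded-random order. Each claims at
most its fair share `pool / n_individuals` of every pool, converted to a
specific rate by dividing by `biomass × timestep` and capped at `vmax`.
Sequential updates guarantee pools never go negative, and the acting
order is reshuffled every hour so no species systematically eats first.
Replicate $r$ runs under `seed + r`; identical inputs and seed give
byte-identical outputs.

## The synthetic community generator

Real gapseq-scale models (thousands of reactions) and the metagenomes
behind them are out of scope; instead the generator assembles toy
communities from a **closed motif library** whose growth optima are
hand-checkable:

- **degrader** (the keystone, a *Bacteroides*-like primary degrader):
  starch/fiber + urea → glucose + succinate + biomass;
- **fermenter**: glucose → lactate;
- **generalist**: glucose or mucin sugar → acetate;
- **butyrate producer**: acetate, lactate, or (inefficiently) glucose →
  butyrate;
- **auxotroph-like propionate producer**: succinate (efficient, cross-fed
  from the keystone) or glucose (inefficient) → propionate.

Every intended producer → metabolite → consumer edge is recorded as
`PlantedTruth`, and the constructor verifies each edge is stoichiometrically
realizable. Keystone-on (HB-like) and keystone-off (NB-like) communities
differ only in the keystone's presence and renormalised abundances, which
gives a controlled contrast: without the degrader the remaining members
converge on the same dietary sugars (higher minimal-medium overlap, MRO)
while a larger fraction of the possible species pairs exchange
fermentation products (higher cross-feeding coefficient, CFC). These two
directions are asserted over seeded paired cohorts in the acceptance
tests, qualitatively mirroring the keystone-removal contrast the method
is designed to expose.

The default diet is a toy corn-feed rendering after upper-gut absorption:
starch reduced by 97% before reaching the cecum, a cellulose-like fiber
that largely escapes absorption, residual free glucose, and host-derived
urea and a mucin sugar (absorption 0). The free-glucose entry is a
generator design choice: without any simple sugar, keystone-free
communities would collapse outright and the group contrast would be a
trivial live-vs-dead comparison rather than a reorganisation of
cross-feeding.

What the generator does **not** emulate: model scale (fixtures stay under
~15 reactions), annotation noise, strain-level variation, incomplete
genomes, or regulatory limits on pathway use. Tests passing on these
fixtures demonstrate that the pipeline's statistics are computed
correctly and respond to planted structure in the intended direction —
not that the biology of a real cecum is reproduced.

## From fluxes to interactions

Per species and metabolite, export and import fluxes are aggregated over
the whole run (averaged over replicates); totals at or below 1e-6
mmol/gDW/h are discarded as numerical noise. A species is a *producer* of
a metabolite if its aggregated export exceeds the threshold, a *consumer*
if its import does; merging the two sets on shared metabolites yields
(producer, consumer, metabolite) rows with producer ≠ consumer.
Thresholding on run-aggregated totals (not hourly values) follows the
definition of the retained fluxes as total exchange over the simulation.

- **CFC** = realised ordered producer→consumer pairs divided by
  $S(S-1)$. The printed definition ("pairs over all possible
  combinations") is ambiguous between pair counts and pair×metabolite
  counts; the ordered-pair reading keeps the coefficient in [0, 1] and is
  used here, while per-metabolite counts remain available as weights.
- **Group pooling** sums interaction counts across samples and normalises
  by the number of samples in which each producer–consumer pair occurs.
- **Hubs** are taxa exchanging ≥ 12 distinct metabolites with ≥ 10
  distinct partners (both roles counted).
- **Cliques**: per-taxon interaction profiles are clustered by
  complete-linkage on Euclidean distances and the tree is cut at a fixed
  k (default 8). A fixed cut replaces visual inspection of the clustered
  heatmap so clique assignment is reproducible.
- **Keystone metabolites** pass three toggleable filters: ≥ 30% of
  production or consumption attributable to a single keystone taxon, ≥ 1%
  of production cross-consumed by another taxon, and distinct top
  producers between the two community groups.

## Community-level metrics

- **Incidence matrices** (samples × reactions/pathways/ECs), binary or
  abundance-weighted; Jaccard distances on binary and Bray–Curtis on
  weighted matrices (via vegan), ordinated by classical PCoA
  (`stats::cmdscale`), with percent variance taken over positive
  eigenvalues.
- **MI**: two samples' binary reaction profiles over a shared universe of
  R reactions are treated as R paired Bernoulli observations;
  MI = Σ p(x,y) ln[p(x,y)/(p(x)p(y))] in nats. In the toy world every
  roster of ≥ 5 species contains all four non-keystone motifs, so binary
  reaction content collapses to two distinct profiles and MI is nearly
  constant across cohorts — a structural property of the closed motif
  library, not of the estimator.
- **CMD**: mean off-diagonal pairwise Jaccard distance between member
  species' EC sets, multiplied by log2(S). The size adjustment is a
  design choice (the "diminishing contribution of additional species"
  read as a logarithmic reward); the unadjusted mean is returned
  alongside so any other adjustment can be applied.
- **MRO**: each member's minimal nutrient set on the diet is computed by
  deterministic greedy elimination in lexicographic metabolite order
  (an exact exhaustive mode exists for ≤ 12 candidates and the tests
  verify the greedy result matches it in cardinality on all fixtures);
  MRO is the mean over unordered pairs of |Mi ∩ Mj| / min(|Mi|, |Mj|).
  Both the greedy-vs-exact choice and the min-normalisation are
  documented decisions, each isolated in a single function.

## Group comparison

Per sample and metabolite, hourly species fluxes are summed, divided by
the total number of individuals at that hour, summed over the 16 h and
averaged over replicates. Group differences are tested per metabolite
with the Wilcoxon rank-sum test (exact enumeration for group sizes ≤ 8
without ties, tie-corrected normal approximation otherwise) and BH-FDR
corrected across metabolites. The fold change is computed on group means
of flux *magnitudes* with a 1e-9 pseudo-count; the sign pattern of the
group means assigns one of six exchange-direction categories (increased
production/consumption in either group, or a production↔consumption
switch between groups). Net fluxes cross zero between groups, so a signed
ratio would be ill-defined — the magnitude-plus-classifier split is the
package's resolution of that ambiguity. A metabolite is labelled only
when q < 0.05 **and** |log2FC| > 0.7.

Predicted concentrations (e.g. SCFAs) can be validated against
measurements with tie-corrected Spearman correlation (exact permutation
p for n ≤ 9 without ties, t approximation otherwise).

## Numerical choices

- LP feasibility 1e-9, optimality 1e-6, growth threshold 1e-4 1/h
  (`cecosim_tolerances()`), flux threshold 1e-6 mmol/gDW/h.
- Infinite bounds are clamped to ±1e6 before solving.
- Zero-growth individuals short-circuit to the all-zero flux vector
  (the parsimonious optimum when the origin is feasible) instead of
  running the second LP.
- Identical FBA subproblems within an hour are memoised: fluxes depend on
  the model only through the bound vector, so individuals facing the same
  bounds share one solve.
- Emptying removes `round(fraction × n_cells)` distinct cells (sampling
  without replacement; the text does not specify, distinct cells make the
  25% exact).
- Division when no neighbouring cell is free is skipped, not queued.

## Problem sizes used in tests and the acceptance script

The shipped checks run the full pipeline at reduced scale — grids of
12×12 to 30×30 cells, 60–300 individuals, 1–2 replicates, 16 iterations,
4–8 samples per cohort — which keeps the whole suite in the minutes
range while leaving every stage (generation, simulation, interaction
extraction, metrics, comparison, reporting) fully exercised. The
simulator's own defaults remain the full-scale conditions (100×100 grid,
1000–5000 individuals, 5 replicates).

## Known limitations

- No host uptake of metabolites (butyrate in particular accumulates), no
  mucosal adhesion, no pH dynamics.
- The motif library is intentionally closed; statistics whose variance
  depends on annotation diversity (MI, CMD) have limited spread across
  synthetic cohorts unless `generate_ec_profiles()` is used to inject
  controlled EC overlap.
- Greedy minimal media can exceed the global minimum cardinality on
  adversarial models; the exact mode exists for small candidate sets and
  the deviation is bounded by tests on all fixtures.
- The simplex is dense and intended for toy-scale models; gapseq-scale
  models (~2000–3000 reactions) would need a sparse LP backend.
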