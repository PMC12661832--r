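# cecosim

Spatial, individual-based dynamic flux-balance simulation of cecal
microbial communities, with the downstream statistics needed to dissect
their cross-feeding structure.

## The problem

Gut communities are organised by metabolic hand-offs: primary degraders
(e.g. *Bacteroides* species) liberate sugars and organic acids from
dietary polymers that other taxa ferment onward to short-chain fatty
acids. Whether such a keystone taxon is present or absent reorganises who
feeds whom, how much species compete for the same resources, and which
taxa act as metabolic hubs. `cecosim` provides an in-silico cecum to
study these questions: each bacterium is an individual on a grid carrying
a genome-scale metabolic model (GEM), hourly growth is computed by
parsimonious flux balance analysis under fair-share nutrient rationing,
the lumen receives a diet influx each hour and is partially emptied every
fourth hour, and the recorded exchange fluxes are distilled into
interaction networks and community metrics.

Core quantities, per community of S species:

- **CFC** (cross-feeding coefficient): realised ordered
  producer→consumer pairs / S(S−1), a pair being realised when both
  sides' run-aggregated exchange flux of a shared metabolite exceeds
  1e-6 mmol/gDW/h.
- **MRO** (metabolic resource overlap): mean over species pairs of
  |Mi ∩ Mj| / min(|Mi|, |Mj|), where Mi is species i's minimal
  growth-supporting nutrient set on the diet.
- **CMD** (community metabolic dissimilarity): mean pairwise Jaccard
  distance between members' EC sets × log2(S).
- **MI**: mutual information between samples' binary reaction profiles
  (nats).
- Hub taxa (≥ 12 metabolites exchanged with ≥ 10 partners), interaction
  cliques (complete-linkage tree cut), keystone-associated metabolite
  filters (30% / 1% / distinct-top-producer), and per-metabolite group
  comparison of community-size-normalised exchange fluxes (Wilcoxon +
  BH-FDR, six exchange-direction categories at |log2FC| > 0.7).

A synthetic community generator with a closed, hand-checkable motif
library (degrader / fermenter / generalist / butyrate producer /
auxotroph) plants known producer→consumer edges and a keystone contrast,
so the entire pipeline is testable without any external data. Models can
also be loaded from SBML Level 3 (fbc) or a compact JSON dialect
(`inst/extdata/model-schema.md`).

## Worked example

```r
library(cecosim)

# a toy fermenter from SBML; glucose uptake capped at 10 mmol/gDW/h
m <- read_model(system.file("extdata", "toy_fermenter.sbml",
                            package = "cecosim"), "sbml")
solve_fba(m, c(glc = 10))
#> <fba_solution> status: optimal
#>   growth rate: 5 1/h
#>   nonzero fluxes: 4 of 4

# a small two-group cohort, simulated end to end
cfg <- pipeline_config(n_hb = 3, n_nb = 3, n_species = 6,
  arena = list(grid_width = 15, grid_height = 15, iterations = 8,
               replicates = 1, community_size_range = c(60, 120)))
res <- run_pipeline(cfg, seed = 5)
res
#> <cecum_pipeline> 6 samples ( 3 HB / 3 NB ), seed 5
#>   mean CFC:  HB 0.1333  NB 0.15
#>   mean MRO:  HB 0.7  NB 0.8
#>   significant metabolites: 0 of 10

res$interactions$HB
#>            producer            consumer metabolite weight n_samples_present
#> 1       fermenter_1 butyrate_producer_1        lac      1                 3
#> 2       fermenter_2 butyrate_producer_1        lac      1                 3
#> 3      generalist_1 butyrate_producer_1         ac      1                 3
#> 4 keystone_degrader         auxotroph_1       succ      1                 3
```

The printed block reads: keystone-off (NB-like) communities show the
higher cross-feeding coefficient (0.15 vs 0.133) and the higher resource
overlap (0.8 vs 0.7) — removing the primary degrader pushes the remaining
members onto the same dietary sugars while a larger fraction of the
possible species pairs exchange fermentation products. The HB interaction
table lists the non-dietary cross-feeding edges (lactate and acetate
flowing to the butyrate producer, keystone-derived succinate to the
propionate producer), each present in all 3 samples. At this toy scale no
per-metabolite flux difference clears the FDR + fold-change labelling
thresholds.

`run_pipeline(..., out_dir = "report/")` writes every table as TSV
(metrics, interactions, hubs, shares, cliques, comparison, MI matrix,
PCoA coordinates) plus a YAML config echo; identical config and seed
reproduce the tables byte for byte. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

## Layout

- `R/` — GEM containers and IO, simplex + FBA + minimal media, diet and
  synthetic-community generators, the arena simulator, interaction
  analysis, community metrics, group comparison, pipeline orchestration.
- `vignettes/cecosim-methods.Rmd` — the model, its assumptions, all
  tunable parameters and the design decisions behind the statistics.
- `tests/testthat/` — unit, property and acceptance tests with
  independent brute-force oracles (LP vertex enumeration, exhaustive
  Wilcoxon/BH/Spearman, histogram MI, naive complete linkage).
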