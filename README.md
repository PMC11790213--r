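# elevclade

Why does species richness on some mountains peak in the lowlands and on
others at mid or high elevation?  `elevclade` is an R package for
researchers in macroevolution and biogeography who want to take that
question apart mechanistically.  It has two halves:

1. **A population-based Gillespie simulator** of an endemic clade
   radiating over a mountain-shaped lattice.  The mountain has four
   concentric elevational bands whose areas shrink toward the top (a
   cone: 58/24/13/5.8% of the area) or not (a plateau with a 40% summit).
   Populations colonize adjacent unsaturated cells (rate γ), go locally
   extinct (rate μ) and bud off new species (band-dependent rate λ);
   cells hold at most K species (the local "niche width"), temperature
   falls 5 °C per band from 20 °C, and colonization can be filtered by
   local adaptation with stabilizing-selection fitness
   `exp(-((T_p - T_c)² / 2V))`.  Scenarios cross K and λ directions
   (increase / decrease / uniform with elevation, 4-fold and 9-fold
   contrasts), local adaptation on/off and lowland/highland origin — 36
   scenarios per landscape shape.  Summary metrics quantify the
   elevational diversity gradient (peak band and strength), dispersal
   provenance (which bands' diversity is immigrant-built), proportional
   range occupancy, temperature mismatch and the richness equilibrium.

2. **A state-dependent diversification (SSE) framework** for empirical
   clades: species elevations are discretized into three equal-width
   bands, and fifteen models — five band-transition structures
   (adjacent-only or any-band, symmetric or asymmetric, all-free) crossed
   with three diversification structures (constant-rate,
   elevation-dependent, concealed-trait-dependent) — are fitted to a
   rooted ultrametric phylogeny by maximum likelihood (pruning with
   adaptive Runge–Kutta integration of the SSE equations) and compared
   with AIC weights, pooled over model families.

## A worked example

Simulate the geometry-only scenario (uniform K and λ on the cone) to its
richness equilibrium and summarize it:

```r
library(elevclade)

cfg <- scenario_config(K_direction = "uniform",
                       lambda_direction = "uniform", seed = 1)
res <- run_simulation(cfg)
res
#> Clade simulation (cone, K uniform, lambda uniform, local adaptation off)
#>   status: equilibrium at time 58.568 after 150000 events
#>   regional richness: 244
#>   per-band richness (lowland->highland): 152, 61, 43, 25
```

Lowlands are the richest band even though per-cell niche width and
per-population diversification are identical everywhere: the 10-fold
larger lowland area alone generates a monotonically decreasing gradient.

```r
edg_strength(res$state$band_richness)
#> $peak_band
#> [1] 0
#> $strength
#> [1] 0.5986842
round(dispersal_provenance(res$state), 2)
#> [1] 0.04 0.18 0.23 0.44
round(proportional_occupancy(res$state), 2)
#> [1] 0.07 0.16 0.23 0.40
```

The three metrics read, lowland to highland: only 4% of lowland species
originated elsewhere against 44% of the highland residents (highland
diversity is immigrant-built); and highland species each hold ~40% of
their band on average against ~7% for lowland species.  Whole scenario grids run
with `enumerate_scenarios()` + `run_grid()`, which derive every
replicate's seed from `(base_seed, scenario_id, replicate)` so results
are independent of execution order.

On the phylogenetic side:

```r
set.seed(2)
spec <- sse_model_spec("a", "CR")   # adjacent symmetric moves, equal rates
sim <- simulate_sse_tree(spec, c(lambda = 0.5, mu = 0.1, q = 0.1),
                         ntip = 60)
fit <- fit_model_set(sim$tree, sim$tip_states, n_starts = 2)
fit$family_weights
#>                  family     weight
#> 1   symmetric_dispersal 0.66764420
#> 2  asymmetric_dispersal 0.33235580
#> 3         adjacent_only 0.94694993
#> 4              any_band 0.05305007
#> 5   elevation_dependent 0.04316600
#> 6 elevation_independent 0.95683400
#> 7         constant_rate 0.93962411
#> 8   concealed_dependent 0.01720989
```

The pooled AIC weights recover the generating model's families: symmetric
dispersal between adjacent bands, with elevation-independent
diversification.  For real data, use `assign_bands()` on a named vector
of species elevations (in meters) and pass the result together with a
newick tree read by `ape::read.tree()`.

Command-line wrappers for single scenarios and full grids live in
`inst/cli/` (`elevclade-simulate`, `elevclade-grid`).

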