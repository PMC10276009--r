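# hidalgoid

Heterogeneous intrinsic dimension (ID) estimation for country-level
time-series panels, with spatial autocorrelation analysis of the
resulting ID map.

## What problem this solves

Concatenating a few daily series per country (say, new cases per
million, new deaths per million, and a policy stringency index over 454
days) produces rows of nominal dimension D = 454 × 3 = 1362.  Such data
are highly redundant: the rows lie near manifolds of far lower
dimension, and *how low* differs between groups of countries — a
country whose deaths closely track its cases and policy needs fewer
effective dimensions than one whose series are weakly coupled.
`hidalgoid` is for analysts who want to (i) estimate that heterogeneous
manifold structure, (ii) group countries by the dimension of the
manifold they lie on, and (iii) test whether the country-level ID map
clusters geographically.

## The model in brief

For locally homogeneous samples on a d-dimensional manifold, the
second-to-first nearest-neighbour distance ratio is density-free:

    mu_i = r_{i,2} / r_{i,1} ~ Pareto(1, d)

Heterogeneity is modelled by an L-component mixture
`f(mu | d, pi) = sum_l pi_l d_l mu^-(d_l + 1)` with Gamma priors on the
`d_l`, a sparse Dirichlet prior (`alpha = 0.05`) on the weights — so the
number of populated components L* ≤ L is estimated, not fixed — and a
local-homogeneity term tying each point's q nearest neighbours to its
cluster with probability `zeta`.  A compiled Gibbs sampler returns label,
weight and ID chains; post-processing is label-switching-proof via the
posterior co-clustering matrix, a Variation-of-Information partition
estimate, and observation-specific ID chains.  Moran's I with binary
contiguity weights and permutation inference quantifies spatial
structure in the per-country median IDs.  Synthetic generators for
multi-manifold point clouds and spatially structured panels make every
stage testable offline.  See the vignette in `vignettes/` for the full
account.

## Worked example

Two latent manifolds — a 2-cube and an 8-cube, 300 points each —
embedded in 20 nominal dimensions, then recovered:

```r
library(hidalgoid)

spec  <- manifold_spec(list(c(2, 300), c(8, 300)), nominal_dim = 20, seed = 42)
cloud <- sample_manifold_mixture(spec)

fit  <- hidalgo(cloud$matrix, hidalgo_config(n_iter = 5000, burn_in = 1000, seed = 7))
part <- vi_partition(coclustering(fit), fit)
part
#> <vi_partition> L* = 2, sizes: 300, 300 (expected VI bound 0.09133)

summarize_id(observation_chains(fit), part)$cluster
#> # A tibble: 2 × 4
#>   cluster n_units mean_id median_id
#>     <int>   <int>   <dbl>     <dbl>
#> 1       1     300    2.36      2.24
#> 2       2     300    7.14      7.15
```

The sampler finds exactly two populated components (L* = 2) splitting
the points 300/300 with posterior mean IDs 2.4 and 7.1 — the 2-manifold
recovered almost exactly, the 8-manifold estimated slightly low, which
is the expected finite-sample behaviour of nearest-neighbour ratio
estimators at that dimension and sample size.

The same machinery end to end on a synthetic spatially structured panel
(36 units on a grid, two graph regions lying on manifolds of latent
dimension 2 and 6):

```r
w     <- synth_adjacency(36, "grid")
edges <- which(w$w == 1 & upper.tri(w$w), arr.ind = TRUE)
sim   <- synth_country_panel(panel_spec(36, 60, 3, latent_dim = c(2, 6),
                                        noise_sd = 0.02, graph = edges,
                                        spatial_field = TRUE, seed = 5))
run_pipeline(sim, hidalgo_config(n_iter = 3000, burn_in = 500, seed = 9),
             weights = w)
#> <hidalgo_report> n = 36 units, D = 180
#>   L* = 2 manifold(s); posterior mean IDs: 5.1, 1.85
#>   Moran's I on median IDs: 0.379 (p = 0.001)
```

Two ID manifolds are recovered and, because regime membership is
constant on graph communities, the per-unit median IDs are positively
spatially autocorrelated (I = 0.38, permutation p = 0.001).

Real panels enter as long-format CSV via `read_panel_csv()` (columns
`unit,date,variable,value`, plus an optional `unit,population` metadata
file) and flow through the same `run_pipeline()` /
`run_stages(stage_windows())` calls; country adjacency comes from a
two-column edge list via `build_weights()` or `read_edges_tsv()`.

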