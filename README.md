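# dmnet: two-layer plant–bird mutualism networks and double mutualisms

On remote oceanic islands, insect scarcity pushes land birds toward floral
resources and fruit, so the same bird species often both pollinates plants
and disperses their seeds — sometimes for the *same* plant species. Such a
plant–bird pair, linked in both the pollination and the seed-dispersal
network, is a **double mutualism**. `dmnet` is an R package for building the
two-layered bipartite network behind this phenomenon, asking whether double
mutualisms are more frequent than expected if the two link types were placed
independently, and quantifying the architecture that double mutualists
create.

The package is for community ecologists working with interaction networks
(pollination webs, frugivory webs, and especially their combination) who
need the full pipeline from edge lists to significance tests in one place.

## What it computes

A network is two binary plant × bird incidence matrices `P` (pollination)
and `S` (dispersal) over a shared species set, optionally weighted (pollen
grains/mm², viable seeds per dropping).

* **Link accounting and roles.** Each linked pair is pollination-only,
  dispersal-only, or a double mutualism (`P_ij = S_ij = 1`, scored as *one*
  link). Every species gets one of four roles: single pollination mutualist,
  single dispersal mutualist, pollinator–disperser (both layers, no shared
  partner), or double mutualist.
* **Connectance** `C = 100·L/(n_P·n_B)` on the total network, on the
  *overlap area* (species active in both layers) and on the
  *double-mutualism submatrix* (species in ≥ 1 double mutualism); a doubled
  denominator `2·n_P·n_B` is available as an alternative convention.
* **Double-mutualism null test.** The scoped subnetwork's two layers are
  randomized independently (fill-preserving by default; degree-preserving
  checkerboard swaps and the Ce cell-probability model are alternatives) and
  the one-tailed p is `#{null ≥ observed}/n`. Under the fill-preserving
  null the coincidence count is exactly hypergeometric, and the closed form
  is reported alongside the Monte-Carlo estimate.
* **Nestedness** NODF (paired overlap with strict decreasing fill, pooled
  over row and column pairs, in [0, 100]) with a 1000-replicate Ce-null z
  and p.
* **Modularity** `M = Σ_s [l_s/L − (d_s/2L)²]` on the union graph, optimized
  by simulated annealing (node moves plus merge/split proposals), with a
  degree-preserving rewiring null.
* **Centrality and strength.** Freeman-scaled betweenness by role group;
  per-layer dependencies `d_ij = w_ij / Σ_j w_ij`, species strength
  `s_j = Σ_i d_ij`, a permutation rank-sum comparison of strength between
  roles, and the cross-layer regression of dispersal on pollination degree
  (`F = t²` of the slope on (1, n−2) df).
* **Synthetic coupled networks.** A seeded generator with
  abundance-driven degrees and a coupling parameter ρ: each dispersal link
  lands on a pollination-linked pair with probability ρ, else uniformly —
  at ρ = 0 the expected double-mutualism count is `fill_P·fill_S/cells`
  exactly, which makes the generator its own oracle for calibration and
  power experiments (`recovery_experiment()`).

## Worked example

`galapagos_network()` rebuilds, deterministically, a network realizing the
published group-level counts of the Galápagos plant–bird mutualism matrix
(species identities are placeholders; every count-level quantity is exact):

```r
library(dmnet)
net <- galapagos_network()
net
#> Two-layer mutualism network: 108 plants x 21 birds
#>   links: 479 total (347 pollination-only, 107 dispersal-only, 25 double mutualisms)
#>   connectance (single convention): 21.12%

link_accounting(net)
#> Links: 479 total | pollination-only 347 (72.44%) | dispersal-only 107 (22.34%) | double 25 (5.22%)

dm_null_test(net, scope = "overlap", n = 50000, seed = 1)
#> Double-mutualism null test (fill_preserving null, overlap scope, 20 x 17)
#>   observed 25 | null 20.79 +/- 3.32 over 50000 randomizations
#>   P(null >= observed) = 0.1327  [(k+1)/(n+1) = 0.1328]
#>   exact hypergeometric p = 0.1318

dm_null_test(net, scope = "dm_submatrix", n = 50000, seed = 2)
#> Double-mutualism null test (fill_preserving null, dm_submatrix scope, 13 x 10)
#>   observed 25 | null 20.09 +/- 2.63 over 50000 randomizations
#>   P(null >= observed) = 0.04652  [(k+1)/(n+1) = 0.04654]
#>   exact hypergeometric p = 0.04552
```

Reading: the 25 observed double mutualisms sit in the upper tail of both
nulls — a weak positive coupling of pollination and dispersal (clearly so
within the 13 × 10 double-mutualism submatrix, p ≈ 0.05) — and connectance
climbs 21% → 46% → 62% from the total matrix through the overlap area into
the submatrix, i.e. double mutualists occupy the link-dense network core.

The same pipeline runs on your own data or on synthetic networks:

```r
records <- read_edge_list("interactions.csv")   # layer,plant,bird[,weight]
net <- build_network(records)

sim <- generate_network(generator_config(seed = 42))
nodf_significance(union_presence(sim), n_null = 1000, seed = 1)
#> NODF = 40.51 | Ce null 28.30 +/- 1.57 (n = 1000) | z = 7.77, P = 0
```

A command-line wrapper (`inst/scripts/dmnet`) exposes the same operations
as subcommands (`build`, `classify`, `connectance`, `dmtest`, `nodf`,
`modularity`, `betweenness`, `strength`, `simulate`, `report`).

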