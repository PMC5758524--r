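---
title: "Methods: two-layer mutualism networks, double mutualisms and their nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-layer mutualism networks, double mutualisms and their nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmnet)
```

## The data model

A two-layer mutualism network couples a pollination and a seed-dispersal
bipartite graph over one shared set of plants and birds: two binary
plant × bird incidence matrices `P` and `S` with identical, lexicographically
ordered margins, optionally carrying positive interaction weights (pollen
grains/mm² and viable seeds per dropping). Conventions, and why:

* **A double mutualism** is a pair with `P_ij = S_ij = 1`. In link totals
  and connectance it is scored as **one** link: the pair of species is the
  unit of interest, not the pair of functions. The alternative reading (each
  layer's links counted separately against a doubled potential
  `2·n_P·n_B`) is a genuinely open convention for multi-layer networks, so
  `connectance(net, "doubled")` exposes it; nothing else in the package
  depends on it.
* **Species names** are whitespace-normalized and matched
  case-insensitively (field datasets mix codes and spellings); the
  first-seen spelling is kept for display. Duplicate records of one edge
  merge by presence-OR and weight-mean, appropriate for a pooled,
  year-round qualitative network.
* **Isolated species are rejected** at construction: an interaction matrix
  only ever contains interacting species. Sub-setting operations
  (`overlap_subnetwork()`, `dm_submatrix()`) are the one exception — they
  retain exactly the species their definition names, even if a retained
  species keeps no link among the retained set (possible only in contrived
  cases).
* The **overlap area** keeps species with ≥ 1 link in *each* layer; the
  **double-mutualism submatrix** keeps species in ≥ 1 double mutualism.
  Both are idempotent and nested (submatrix ⊆ overlap ⊆ total), which the
  tests assert as properties.
* Reported percentages are rounded **half away from zero**
  (`round_half_up()`): this is what report-style figures such as 47.6 → 48
  use; `base::round()`'s half-to-even would not reproduce them. Raw values
  are always retained; rounding is applied only at the reporting surface.

## The double-mutualism test

The question: given how many links each layer has, are coincident pairs
more frequent than independent placement predicts? `dm_null_test()`
randomizes both layers of the scoped subnetwork independently `n` times and
reports the one-tailed `p = #{null DM ≥ observed DM}/n`, ties counting
toward the tail, plus the `(k+1)/(n+1)` estimator, which cannot be zero at
finite `n`.

Three nulls are implemented:

* **fill-preserving** (default): each layer's links are placed uniformly at
  random without duplicates, fixing only the layer totals. "Randomizing the
  spread of links" is read this way because it conditions on exactly the
  quantities the question takes as given. Under this null the coincidence
  count between a fixed set of `l_P` cells and a uniform set of `l_S` cells
  in `N` cells is **hypergeometric**, so the exact tail
  `P(X ≥ obs)` (`dm_exact_p()`) is reported next to the Monte-Carlo
  estimate — an internal consistency check and a convergence reference.
* **degree-preserving**: a chain of random 2 × 2 checkerboard swaps
  preserves every species' degree in both margins; stricter, for asking the
  question conditional on generalism structure.
* **Ce**: each cell is an independent Bernoulli draw with probability
  `(rowfill_i + colfill_j)/2`; the mean cell probability equals the matrix
  fill exactly (asserted in the tests), so fill is preserved in
  expectation only.

Scope is a real choice. Randomizing within the overlap area
(`scope = "overlap"`) asks the question among all species engaged in both
functions; randomizing the double-mutualism submatrix within its own
dimensions and link totals (`scope = "dm_submatrix"`) asks it among the
double mutualists themselves. Both are provided because the two analyses
answer different conditionals; whether a published analysis re-scoped one
randomization or ran two cannot generally be recovered from a text, and the
package asserts neither reading as canonical.

Every stochastic operation in the package takes an explicit integer `seed`
and restores the caller's RNG state afterwards; an absent seed is an error,
not a silent default, so no result can be accidentally irreproducible.

## NODF

`nodf()` implements the paired-overlap, decreasing-fill nestedness metric.
For two rows with degrees `d_i ≠ d_j` (both > 0) the contribution is
`100 · |shared partners| / min(d_i, d_j)`; **equal degrees contribute 0**
(the strict decreasing-fill rule) and an empty member contributes 0. The
statistic is the pooled mean over all `C(R,2)` row pairs and `C(C,2)`
column pairs, hence in [0, 100] and invariant to row/column permutation.
Empty rows and columns are kept, not dropped, so the metric is defined
deterministically on degenerate null draws. Two-layer networks are nested
on the **union matrix** (a link in either layer); nesting layers separately
is possible via `layer_presence()` but the union is what a "total network"
analysis means. Significance uses 1000 Ce draws, one-tailed toward high
nestedness with ties in the tail; a null with zero variance is reported
with `z = NA` rather than an error. The implementation is checked against
brute-force enumeration of *every* binary matrix up to 4 × 4 and against an
independent implementation (`vegan::nestednodf`) on larger random matrices.

## Modularity by simulated annealing

The two-layer network is collapsed to one undirected simple **union graph**
(nodes = all species, an edge if linked in either layer), and Newman
modularity `M = Σ_s [l_s/L − (d_s/2L)²]` is maximized by simulated
annealing: per temperature step, `f·n²` single-node moves and `f·n`
collective moves (merge of two modules, or a random bisection split),
accepted with probability `exp(ΔM/T)` when downhill. The schedule defaults
to `T₀ = 1/(2L)` — the scale at which a single-link gain `ΔM ≈ 1/L` is
accepted with probability `e⁻²` — with geometric cooling 0.995 down to
`10⁻³·T₀`, and 3 independent restarts. The best partition encountered is
returned, never worse than the single-module baseline `M = 0`; ties are
first-found under the seeded order. `f` is the effort knob: 0.25 is right
for graphs of tens of nodes (where the annealer provably reaches the
exhaustive-partition optimum — tested by full enumeration on all graphs we
try up to 8 nodes), and the acceptance script uses `f = 0.02` on the
129-node reconstruction, a problem size where one run takes seconds.

Significance compares `M` with `n_random` degree-preserving rewirings of
the graph (a fill-only `gnm` null is selectable), each optimized with the
same schedule; `p = #{M_random ≥ M_obs}/n_random`. Bipartite-specific
modularity (Barber's Q) and role cartography are out of scope: the analysis
this package supports reports `M` and its null only.

## Centrality, dependence, strength

Betweenness is shortest-path betweenness on the unweighted union graph with
Freeman scaling `2/((n−1)(n−2))`, because the interesting quantity is how
species bridge the two functional layers; per-layer betweenness is an
option. The table carries each species' role so role-group means fall out
directly. The igraph routine stands behind the computation; tests check it
against a hand-rolled BFS path-enumeration oracle.

Quantitative comparisons stay **within one layer** — pollen loads and seed
counts have no defensible exchange rate, so the package never merges the
two weight currencies. Dependency of plant `i` on bird `j` is
`w_ij / Σ_j' w_ij'` (rows of active plants sum to 1 exactly), strength of a
bird is the sum of its partners' dependencies on it, and bird strengths sum
exactly to the number of weighted plants — both identities are asserted
exactly on generated networks. Strength between role groups is compared by
a two-sided rank-sum statistic with a label-permutation null (≥ 10,000
seeded permutations), avoiding distributional assumptions on strongly
skewed strengths; the permutation p is validated against exact enumeration
on small groups. Cross-layer linkage coupling is an OLS regression of
dispersal degree on pollination degree for species active in both layers,
reported as `r` and `F = t²` on `(1, n−2)` df.

## The synthetic generator

`generate_network()` emulates the features of island plant–bird data that
the pipeline is sensitive to: two binary layers over shared species,
**abundance-driven degree heterogeneity** (cell probabilities proportional
to plant × bird log-normal abundances; more abundant birds make more
interactions), a **coupling parameter ρ** (each dispersal link lands on a
pollination-linked pair with probability ρ, else uniformly on a free cell;
collisions redraw with a bounded retry), and overdispersed log-normal
weights. Coupling acts at link placement, not by post-hoc swaps, so at
ρ = 0 the double-mutualism count is exactly the hypergeometric coincidence
law with mean `fill_P·fill_S/N` — a closed-form oracle the tests use. At
ρ = 1 with `fill_S ≤ fill_P` every dispersal link coincides (note the
retry bound: full coupling with `fill_S` close to `fill_P` leaves few free
pollination pairs for the last links, so power designs use
`fill_S < fill_P`). Species ending with no link in either layer are
dropped, as in field matrices; realized species counts can fall slightly
below nominal.

Defaults are the study conditions of the motivating system: 108 plants,
21 birds, layer totals 372 and 132, abundance log-sd 1, and ρ = 0.03 — the
coupling at which the expected coincidence count equals the observed 25,
given the independence expectation of 21.7. The generator does **not**
emulate phenology or season structure, spatial/island structure, trait
matching, or sampling effort — so passing calibration on it shows the test
is correct under its own assumptions, not that field data meet them.

## Calibration and power designs

The type-I design was fixed analytically before running: the attained level
of the test equals the null tail probability at the largest achievable
critical value, and because the coincidence count is integer-valued the
attained level sits *below* the nominal α by up to one probability step.
The step near the 5% tail is ≈ `0.103/sd(DM)`, so the design needs a wide
null: 30 × 20 cells with fills 180/180 gives `sd ≈ 5.2`, a predicted
attained level of 0.043 with 400 draws per test, and 1000 replicates put
the Monte-Carlo standard error at 0.006. The observed rate (≈ 0.042–0.046
across seeds) is asserted within [0.03, 0.07]. Power and monotonicity use
the same cells with fills 180/90 over ρ ∈ {0, 0.3, 0.6, 1}: rejection is
essentially 0.04 at ρ = 0 and 1 from ρ = 0.3 on.

## The count-level reconstruction

`galapagos_network()` rebuilds a network realizing the published
group-level link totals of the Galápagos plant–bird matrix (role groups
61/13/7/27 plants × 2/10/7/2 birds; 347 + 107 + 25 links). Links are laid
out deterministically inside each role-group block, with coverage diagonals
guaranteeing every species the links its role requires and all link kinds
on distinct cells. Everything that depends only on those totals is exact —
accounting, role shares, the three connectances (21.12 → 45.88 → 62.31%,
printed 21/46/62), and the fill-preserving double-mutualism test, whose
null depends only on scope dimensions and layer totals (exact tails 0.1318
in the 20 × 17 overlap and 0.0455 in the 13 × 10 submatrix). Quantities
that depend on *which* cells are linked — NODF, modularity, betweenness,
degree correlations — are well-defined on the reconstruction but are not
estimates of the field network's values (the species-level link lists are
not bundled); those metrics are validated against oracles on synthetic
networks instead, and the acceptance script reports the reconstruction's
own values descriptively.

## Numerical conventions and degenerate inputs

* Species order is lexicographic everywhere, including exports, so every
  artifact is byte-reproducible under a fixed seed.
* One-tailed p-values are plain fractions with ties in the tail; z-scores
  are `NA`, not errors, when a null ensemble has zero variance.
* Zero-dimension networks: `connectance()` and the null test error
  (meaningless denominators, empty scope); `link_accounting()` returns
  zeros; sub-setting returns valid empty networks.
* Weight rows with zero totals yield all-zero dependency rows and are
  flagged by name rather than producing NaN.
* Degree-preserving swaps on matrices with no checkerboard (e.g. full
  columns) correctly return the input unchanged.

## Problem sizes in the tests and acceptance script

The default test run enumerates all ≤ 4 × 4 matrices for NODF, all
partitions of ≤ 8-node graphs for modularity, 1000 calibration replicates
of 400 draws, and two 50,000-draw null tests; the whole suite runs in about
two minutes and the acceptance script in under a minute on one core. These
sizes are the package's own choices, picked so each check has the
statistical resolution its assertion needs (3 standard-error margins
throughout).

## Known limitations

* The annealer's solution quality at `f` far below 0.25 on large graphs is
  not guaranteed; for publication-grade partitions of big networks, raise
  `f` and `restarts`.
* The degree-preserving null for the two-layer test randomizes each layer's
  margins separately; a null preserving joint plant-level constraints
  across layers is not implemented.
* Weighted null models and weighted nestedness (WNODF) are deliberately out
  of scope; the coincidence question is about binary link placement.
* The generator's independence oracle assumes exact fills; if a requested
  fill is infeasible the constructor errors rather than approximating.
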