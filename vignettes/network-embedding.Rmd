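---
title: "Flexible random-walk embedding of one network into another"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible random-walk embedding of one network into another}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(flexembed)
```

## The model

`flexembed` implements a generative null model for coupling two network
layers: a large network A (think: a social network of `N_A` individuals) is
*embedded* into a small network B (think: `N_B` spatially adjacent
locations), meaning every A-node receives exactly one B-location. Each
location `i` carries an attractiveness `f_i > 0`, normalized so
`sum(f) = 1` — its probability of receiving mass, e.g. proportional to city
population.

The assignment rule repeats until every A-node is placed:

1. pick an unassigned **source** node of A uniformly at random and assign
   it to a **target** location drawn from `f`;
2. for each *currently unassigned* neighbor of the source in A, launch an
   independent random walk on B from the target. At every step the walk
   halts with probability `q`, and otherwise hops from location `j` to
   neighbor `i` with probability `C[i, j] = f_i B_ij / sum_l f_l B_lj`.
   The neighbor is assigned wherever its walk halts.

Neighbors placed in a step do not recruit their own neighborhoods; one
"step" of model time is one source selection. The single parameter `q`
tunes locality: at `q = 1` the walk never moves and each step's batch lands
on one location (the most local coupling); as `q -> 0` the walk forgets its
start and halts according to the stationary distribution `v0` of `C` (the
most delocalized coupling). The `q = 0` limit is implemented by sampling
walker-placed nodes directly from `v0` — no infinite walks are simulated.

Two outputs summarize a completed embedding: the realized populations
`phi_i` (number of A-nodes at location `i`) and the embedded weighted
network `Gamma`, where `Gamma[i, j]` counts A-edges between the groups at
locations `i` and `j` (diagonal: within-location edges). Every realization
satisfies `sum(phi) = N_A` and `sum over i <= j of Gamma[i, j] = |E_A|`
exactly — the conservation laws the test suite asserts run by run.

### Walk semantics

The halt test precedes the first hop, so a walk returns its start with
probability at least `q`, and `q = 1` is exactly the fully local limit.
This stop-before-move convention is forced by the closed forms below: the
halting distribution of a walk started at `j` is column `j` of
`q (I + Omega(q))`, with `Omega(q) = sum_{r >= 1} (1 - q)^r C^r` carrying
the `r >= 1` hops and the `q I` term the halt-in-place mass. The simulator,
the propagator, and the predictions all share this convention, and the
tests verify the empirical halting distribution against the analytic
columns.

## Spectral layer

`transition_matrix()` builds the column-stochastic kernel `C`;
`walk_propagator()` evaluates `Omega(q)` in closed form as
`(1 - q) C (I - (1 - q) C)^{-1}` via one dense solve (the geometric series
converges since the spectral radius of `C` is 1); the truncated series is
kept in the test suite as an independent oracle, never used in production.
Columns of `Omega(q)` sum to `(1 - q) / q`, a useful invariant: the
expected number of hops of a killed walk. `stationary_distribution()`
returns the eigenvalue-1 eigenvector, L1-normalized, with a lazy-walk
power-iteration refinement that also covers bipartite B (a path graph, for
example), where only the stationary vector — not chain convergence — is
needed. Dense linear algebra is the right tool here because the model
premise is `N_A >> N_B`: location networks are small by design.

Disconnected B is rejected rather than handled per component, since the
stationary distribution (and hence the `q = 0` limit) is not unique there.

## Mean-field description of the assignment process

The analytics need only the degree moments of A. Writing `eta(t)` for the
number of unassigned nodes at continuous time `t` (one source selection per
unit time), `k1(t)` and `k2(t)` for the first two moments of the number of
*unassigned* neighbors of an unassigned node, and `kd(t)` for the mean
number of *assigned* neighbors, the moment equations are

```
k1' = (k1^2 - 2 k2) / (eta - 1 - k1)
k2' = (k2 (1 - 2 k1 - 2 k2 / k1) + 2 k1^3) / (eta - 1 - k1)
kd' = k2 / (eta - 1 - k1)
```

with `eta' = -(1 + k1)` — each step removes one source plus, on average,
its `k1` unassigned neighbors — and initial conditions
`eta(0) = N_A, k1(0) = <k>_A, k2(0) = <k^2>_A, kd(0) = 0`. The completion
time `t*` is fixed implicitly by `N_A = int over [0, t*] of (1 + k1) dt`.
The derivation assumes a locally tree-like network with no degree-degree
correlations.

`integrate_moments()` uses classical fixed-step RK4 (default step 0.1 of a
source selection; halving the step moves every summary by less than 1e-6
relative, a check exposed as `integration_convergence()`). The running
integrals are carried as augmented RK4 states so they share the
trajectory's fourth-order accuracy and its grid.

### The terminal singularity

The shared denominator `eta - 1 - k1` vanishes as the process completes,
and shortly before that the variance `k2 - k1^2` crosses zero, past which
the equations lose their moment interpretation and blow up (`k2` turns
negative and `k1` re-inflates). Integration therefore halts at the first
step that cannot be completed — a stage denominator at or below the guard
(default `1e-6 N_A`) or a new state with `k2 < k1^2` — with the failing
step bisected down to a floor so the halt lands on the breakdown frontier
independently of the nominal step size. Roundoff-scale moment violations
(below 1e-9) are clamped; real ones stop the integration. Past the halt,
`t*` is resolved by extending `int (1 + k1) dt` linearly to `N_A`, and the
same constant-value tail feeds every integral summary. This makes
`t* + alpha = N_A` hold to machine precision by construction.

### Integral summaries and the edge-mass identity

All predictions are built from integrals over `[0, t*]`:
`alpha = int k1 dt` (expected number of walk-placed nodes),
`beta = int (k2 - k1 + k1 kd) dt` and `gamma = int kd dt` (stub counts of
the asynchronous pairing), and `delta(q) = t* + q alpha`. Exact edge
accounting requires `2 alpha + beta + gamma = N_A <k>_A`: every A-edge is
either placed synchronously (one per walk, `alpha` in total) or leaves two
stubs.

Under the moment equations this identity is *not* exact: a short
calculation gives

```
d/dt [2 alpha + beta + gamma + eta (k1 + kd)] = -(k2 - k1^2)(1 + k1) / (eta - 1 - k1),
```

a strictly negative leak while the variance is positive, amounting to a
fraction of a percent of the total edge mass on sparse random graphs.
`moment_summaries()` therefore reports `gamma` from the identity
`gamma = N_A <k>_A - 2 alpha - beta` — which makes the predicted embedded
network conserve `|E_A|` exactly — and keeps the direct quadrature as
`gamma_quad` for diagnosis; the tests require the two to agree within a
couple of percent.

### Accuracy of the closure, honestly stated

The moment equations are a leading-order closure, and their accuracy
depends on the degree structure of A. Exact one-step accounting for a
configuration-model pool gives a drift of `k1` proportional to
`k1^2 + k1 - 2 k2` and of `kd` proportional to `k2 - k1`; the equations
above omit the `O(k1)` terms, which is immaterial when `k2` dominates
`k1^2` (heavy-tailed degree distributions, e.g. preferential-attachment
trees) but material for Poisson-like graphs where `k2 ~ k1 + k1^2`. For an
Erdos-Renyi layer with `N_A = 1000, p = 0.01` the closure predicts a
completion time near 303 steps while direct simulation (and the
self-consistent thinning argument `t* = log(1 + (N_A - 1) p) / p`) gives
close to 240; `scripts/acceptance.R` recomputes both numbers
(`t_star_meanfield`, `t_star_simulated_mean`) on every run. The bias
propagates into `alpha` and is the single driver of every
simulation-versus-theory gap the acceptance checks report: ensemble moment
traces sit several standard errors from the integrated trajectories at
mid-process, and the `q = 0` population predictions — whose error is
exactly `(alpha_mf - alpha_sim)(v0 - f)` — miss the 3-standard-error band
on a minority of nodes. Checks that do not lean on the absolute value of
`alpha` (conservation laws, the `q = 1` populations, the spectral layer,
the `q = 0.5` reference experiment where profile differences are small
against ensemble spread, locality monotonicity) pass cleanly at desk
scale.

## Predictions

For `q` in (0, 1), expected populations are
`phi_mean = f delta(q) + q alpha Omega(q) f`; at `q = 1` this collapses to
`N_A f`, and in the `q = 0` limit to `f (N_A - alpha) + alpha v0`. The
expected embedded network adds two contributions: a synchronous matrix
`psi` for edges placed in one step (total mass `alpha` at every `q`) and a
random pairing of the stub vector (total mass `beta + gamma`), giving
`<Gamma> = psi + outer(stubs, stubs) / sum(stubs)`, with the printed
`(1 - delta_ij / 2)` convention so the diagonal counts each within-location
edge once — the same convention as the simulator, which is what makes the
conservation identities comparable entrywise. At `q = 1` a direct closed
form (diagonal `alpha f_i`, off-diagonal `f_i f_j (N_A <k>_A - 2 alpha)`)
is used and verified against the general assembly to 1e-10 at run time.

All summaries feeding one prediction come from a single trajectory, so the
identity ties the pieces together; expected values are real-valued, never
rounded.

## Ensembles, comparisons, and the pipeline

`run_ensemble()` accumulates entrywise means and standard errors over
independent realizations, either on a fixed A or regenerating A per
realization (`a_generator`), the protocol of the reference experiment.
`compare_tables()` forms z-scores `(simulated mean - predicted) / SE` per
population entry and per embedded-weight entry (upper triangle plus
diagonal, self-loops flagged). Entries that cannot support a z-score are
excluded from the summary fractions and labeled: both-exactly-zero entries
as `structural_zero`, zero-SE entries as `degenerate_se` (tiny-weight
cells that no realization hit at the given ensemble size). `glance()`
reports the `|z| < 3` fractions; `autoplot()` draws the
simulation-versus-theory scatter.

`run_pipeline()` drives the whole workflow from a YAML configuration (see
`inst/extdata/reference_experiment.yaml`) with full determinism: stage
seeds are derived from the base seed by fixed offsets, per-realization
seeds by index, and the configuration echo records the RNG kind. A thin
command-line wrapper ships in `inst/scripts/flexembed`.

## Synthetic study conditions

The reference conditions used across the tests and the acceptance script
are an Erdos-Renyi layer A with `N_A = 1000` and edge probability 0.01
(regenerated per realization), a 50-node Voronoi-adjacency location
network on the unit square, and attractiveness sampled from
Uniform(1, 100) then rescaled — a small spatial system with realistic
two-orders-of-magnitude spread in location weights. Ensemble sizes are 500
runs for the closed-form limits and 200 for the intermediate-`q`
experiment, chosen so that desk-scale runs finish in minutes while keeping
standard errors small enough for 3-SE checks to bite. The trace-fidelity
check uses a single fixed A so the `t = 0` trace equals the exact degree
moments.

The Voronoi generator joins points whose Voronoi cells share a boundary,
computed as Delaunay neighborship by the brute-force empty-circumcircle
test over point triples — exact in general position, `O(n^3)` triples, and
entirely adequate for location networks of tens of nodes. Degenerate
configurations are resampled with a message; boundaries are open (no
periodic wrapping). The result is always connected and planar, which the
tests assert.

What these synthetic conditions do *not* emulate: clustering,
degree-degree correlations, and community structure in A (the mean-field
derivation assumes their absence, so agreement there says nothing about
strongly clustered social networks); weighted or directed layers; and any
feedback from the embedding to the networks. Passing tests demonstrate
internal consistency of simulator and analytics under the stated
assumptions, not fidelity to any particular empirical system.

## Numerical choices, edge cases, limitations

* Node indices are 1-based inside R (the igraph convention) and 0-based in
  every file format, converted at the I/O boundary.
* Attractiveness is accepted unnormalized and rescaled; zero or negative
  weights are rejected rather than dropped.
* `N_A <= N_B` draws a warning, not an error: the analytics assume
  `N_A >> N_B` but the simulator is exact at any size.
* Isolated B-nodes are rejected for `0 < q < 1` (the walk kernel is
  undefined there) and disconnected B for `q = 0`; at `q = 1` the topology
  of B is irrelevant and neither restriction applies.
* A single-node B, an edgeless A, and one-edge A are all valid degenerate
  inputs with closed-form outcomes; the tests pin them.
* Variances and full distributions of `phi` and `Gamma` are out of scope:
  the analytics predict means only.
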