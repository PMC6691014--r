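# flexembed

Embedding one network into another with tunable locality — an analytically
tractable null model for inter-layer coupling.

Many systems pair a large "activity" network with a small "location"
network: a social network of individuals over a network of spatially
adjacent counties, patients over a hospital-transfer network, users over a
server topology. `flexembed` implements a generative model for the
coupling itself: every node of the large network A is assigned to a node
of the small network B by a stochastic rule whose single parameter, the
stopping probability `q`, interpolates between perfectly local coupling
(`q = 1`: neighbors end up together) and fully delocalized coupling
(`q -> 0`: neighbors scatter by the stationary measure of a biased walk).
The package provides both the exact simulator and the model's closed-form
expectations, so simulation and theory can be generated, compared, and
reused as a null model.

## The model in brief

Network B carries per-node attractiveness `f_i > 0`, `sum(f) = 1`. Until
all of A is assigned:

1. an unassigned **source** node of A, chosen uniformly, is assigned to a
   target location drawn from `f`;
2. each currently unassigned neighbor of the source follows an independent
   random walk on B started at the target, halting at each step with
   probability `q` and otherwise hopping `j -> i` with probability
   `C_ij = f_i B_ij / sum_l f_l B_lj`; it is assigned where its walk halts.

Outputs per realization: realized populations `phi_i` (A-nodes per
location, `sum(phi) = N_A` exactly) and the embedded weighted network
`Gamma`, with `Gamma_ij` counting A-edges between the groups at locations
`i` and `j` (`sum of upper triangle + diagonal = |E_A|` exactly).

The analytics rest on three ingredients:

* a **spectral layer** for B: the column-stochastic kernel `C`, the
  discounted propagator `Omega(q) = sum_{r>=1} (1-q)^r C^r` (one dense
  solve), and the stationary distribution `v0`;
* **mean-field moment equations** for the assignment process on A,
  integrated with RK4 up to the completion time `t*`, yielding the
  integral summaries `alpha, beta, gamma, delta(q)`;
* **closed-form expectations** assembled from both:
  `<phi> = f delta(q) + q alpha Omega(q) f` (with `N_A f` at `q = 1` and
  `f (N_A - alpha) + alpha v0` at `q = 0`) and
  `<Gamma> = psi + stub pairing`, splitting synchronous (same-step) from
  asynchronous (stub-paired) edges.

## Worked example

```r
library(flexembed)

b <- generate_voronoi(50, seed = 1)                      # spatial location network
f <- sample_attractiveness(50, low = 1, high = 100, seed = 2)
a <- generate_er(1000, 0.01, seed = 3)                   # the large layer

run <- run_embedding(a, b, f, q = 0.5, seed = 4)
run
#> <embedding_realization> N_A = 1000 -> N_B = 50, q = 0.5, 237 steps, |E_A| = 4991
glance(run)
#> # A tibble: 1 × 6
#>     n_a   n_b     q n_steps n_edges_a self_loop_share
#>   <dbl> <dbl> <dbl>   <int>     <dbl>           <dbl>
#> 1  1000    50   0.5     237      4991           0.108
```

One run of the embedding took 237 source selections; 10.8% of the embedded
edge weight fell on self-loops (within-location edges) at this
intermediate locality. Now the analytic expectation and a
simulation-versus-theory comparison:

```r
pred <- embedding_prediction(a, b, f, q = 0.5)
pred
#> <embedding_prediction> q = 0.5 (general-q), N_A = 1000 over 50 locations; self-loop share 0.099

ens <- run_ensemble(a, b, f, q = 0.5, n_realizations = 100, seed = 5)
cmp <- compare_tables(ens, pred)
cmp
#> <embedding_comparison> q = 0.5 (general-q), 100 runs
#>   populations: 50 entries, |z|<3 fraction 0.980 (0 excluded)
#>   edge weights: 1275 entries, |z|<3 fraction 0.973 (1 excluded)

autoplot(cmp)   # predicted vs simulated, self-loops highlighted
```

98% of location populations and 97% of embedded edge weights sit within 3
standard errors of the closed forms at this ensemble size. The mean-field
summaries behind the prediction:

```r
moment_summaries(integrate_moments(degree_moments(a)))
#> <embedding_summaries> N_A = 1000, <k>_A = 9.982
#>   t* = 302.859  alpha = 697.141  beta = 6635.75  gamma = 1951.97 (quadrature 1943.38)
```

`alpha` is the expected number of nodes placed by walks, `t*` the
completion time in source selections. The moment equations are a
leading-order closure: the package vignette quantifies where that
approximation is tight and where it is not (the simulated completion time
for this configuration is near 240 steps, and the acceptance script
reports both numbers side by side).

A YAML-driven pipeline reproduces the full experiment (fresh A per
realization, several `q` values, CSV + JSON artifacts):

```r
cfg <- read_run_config(system.file("extdata/reference_experiment.yaml", package = "flexembed"))
res <- run_pipeline(cfg, out_dir = "runs/reference")
res$report
```

A thin CLI over the same functions ships in `inst/scripts/flexembed`
(subcommands `generate`, `simulate`, `predict`, `pipeline`).

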