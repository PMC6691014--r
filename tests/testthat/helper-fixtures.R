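# Shared fixtures and independent oracles.

# Stationary distribution of the weighted walk, by the strength closed form:
# the kernel C[i, j] = f_i B_ij / sum_l f_l B_lj is the walk on the weighted
# graph w_ij = f_i f_j B_ij, whose stationary measure is the node strength.
# Kept independent of stationary_distribution(), which uses an eigensolver.
v0_strength_oracle <- function(graph_b, f) {
  f <- as.numeric(as_attractiveness(f))
  adj <- as.matrix(igraph::as_adjacency_matrix(graph_b, sparse = FALSE))
  s <- f * as.numeric(adj %*% f)
  s / sum(s)
}

# Truncated-series evaluation of the discounted propagator.
omega_series_oracle <- function(C, q, rmax = 200) {
  n <- nrow(C)
  acc <- matrix(0, n, n)
  pow <- diag(n)
  for (r in seq_len(rmax)) {
    pow <- pow %*% C
    acc <- acc + (1 - q)^r * pow
  }
  acc
}

# Total embedded edge mass (upper triangle + diagonal, each edge once).
gamma_total <- function(gamma) {
  sum(gamma[upper.tri(gamma)]) + sum(diag(gamma))
}

fixture_b <- function() generate_voronoi(10, seed = 303)
fixture_f <- function(n = 10) sample_attractiveness(n, seed = 404)
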