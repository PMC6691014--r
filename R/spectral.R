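#' Transition matrix of the attractiveness-weighted walk on B
#'
#' Column-stochastic hop kernel `C[i, j] = f[i] B[i, j] / sum_l f[l] B[l, j]`:
#' a walker at node `j` steps to neighbor `i` with probability proportional
#' to `i`'s attractiveness. Columns index the current node, rows the next
#' one.
#'
#' @param graph The location network B, undirected, with no isolated nodes.
#' @param f Attractiveness weights (normalized internally).
#' @return A dense `n x n` column-stochastic matrix with the sparsity
#'   pattern of B's adjacency.
#' @export
transition_matrix <- function(graph, f) {
  validate_graph(graph)
  f <- as_attractiveness(f)
  n <- igraph::vcount(graph)
  if (length(f) != n) {
    abort(sprintf("length(f) = %d does not match the %d nodes of B", length(f), n))
  }
  adj <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = FALSE))
  weighted <- adj * as.numeric(f) # scales row i by f[i]
  norm <- colSums(weighted)
  if (any(norm == 0)) {
    abort(sprintf(
      "node(s) %s of B are isolated; the walk kernel is undefined there",
      paste(which(norm == 0), collapse = ", ")
    ))
  }
  sweep(weighted, 2, norm, "/")
}

#' Discounted walk propagator
#'
#' `Omega(q) = sum_{r >= 1} (1 - q)^r C^r`, the expected visit mass of a
#' walk that survives each step with probability `1 - q`. Evaluated in
#' closed form as `(1 - q) C (I - (1 - q) C)^{-1}` through a dense linear
#' solve; the geometric series converges because the spectral radius of a
#' stochastic matrix is 1. Column `j` of `q * (I + Omega(q))` is the halting
#' distribution of a walk started at `j` with stop-before-move semantics.
#'
#' @param C Column-stochastic transition matrix from [transition_matrix()].
#' @param q Stopping probability in `(0, 1]`; at `q = 1` the propagator is
#'   the zero matrix (the walk never moves).
#' @return A dense nonnegative matrix whose columns sum to `(1 - q) / q`.
#' @export
walk_propagator <- function(C, q) {
  check_transition_matrix(C)
  if (!(length(q) == 1 && q > 0 && q <= 1)) {
    abort("q must lie in (0, 1]; the q -> 0 limit is stationary_distribution()")
  }
  n <- nrow(C)
  if (q == 1) {
    return(matrix(0, n, n))
  }
  s <- 1 - q
  s * C %*% solve(diag(n) - s * C)
}

#' Stationary distribution of the weighted walk
#'
#' The eigenvalue-1 eigenvector of `C`, L1-normalized to a probability
#' vector; unique by Perron-Frobenius when B is connected. This is the
#' limiting halting distribution of the assignment walk as `q -> 0`, used
#' directly to place walker-assigned nodes in that limit. Computed with a
#' dense eigensolver, refined (or replaced, if the eigensolver misbehaves)
#' by lazy-walk power iteration, which also covers bipartite B where the
#' plain chain does not mix but the stationary vector is still unique.
#'
#' @param C Column-stochastic transition matrix.
#' @param tol Residual tolerance on `max |C v - v|`.
#' @return A nonnegative numeric vector summing to 1.
#' @export
stationary_distribution <- function(C, tol = 1e-12) {
  check_transition_matrix(C)
  n <- nrow(C)
  pattern <- igraph::graph_from_adjacency_matrix(C > 0, mode = "directed")
  comp <- igraph::components(pattern, mode = "strong")
  if (comp$no > 1) {
    abort(sprintf(
      "B is disconnected (%d components: %s); the stationary distribution is not unique",
      comp$no, paste(comp$membership, collapse = " ")
    ))
  }
  eig <- eigen(C)
  idx <- which.min(abs(eig$values - 1))
  v <- eig$vectors[, idx]
  if (abs(eig$values[idx] - 1) > 1e-6 || max(abs(Im(v))) > 1e-8 * max(abs(Re(v)))) {
    v <- rep(1 / n, n) # fall through to power iteration from scratch
  }
  v <- Re(v)
  v <- v / sum(v)
  v[v < 0 & v > -1e-12] <- 0
  # lazy-walk refinement: (C + I)/2 has the same eigenvalue-1 eigenvector
  # and is aperiodic, so this converges for bipartite B too
  for (iter in seq_len(100000)) {
    if (all(v >= 0) && max(abs(C %*% v - v)) < tol) break
    v <- as.numeric((C %*% v + v) / 2)
    v <- v / sum(v)
  }
  if (max(abs(C %*% v - v)) > 1e-10) {
    abort("stationary distribution failed to converge")
  }
  as.numeric(v)
}

check_transition_matrix <- function(C) {
  if (!is.matrix(C) || nrow(C) != ncol(C)) {
    abort("C must be a square matrix")
  }
  if (any(C < 0) || max(abs(colSums(C) - 1)) > 1e-10) {
    abort("C must be column-stochastic (nonnegative, columns summing to 1)")
  }
  invisible(C)
}

#' Analytic halting distribution of the assignment walk
#'
#' Column `start` of `q (I + Omega(q))` for `q > 0`, or the stationary
#' distribution for `q = 0`: the probability that a walk launched at
#' `start` halts at each node of B. The stop test precedes the first hop,
#' so the start node always retains at least probability `q`.
#'
#' @param graph Location network B.
#' @param f Attractiveness weights.
#' @param q Stopping probability in `[0, 1]` (`0` means the limit).
#' @param start 1-based start node, or `NULL` for the full matrix.
#' @return A probability vector (or matrix of column distributions when
#'   `start = NULL`; for `q = 0` every column is the stationary vector).
#' @export
halting_distribution <- function(graph, f, q, start = NULL) {
  f <- as_attractiveness(f)
  C <- transition_matrix(graph, f)
  n <- nrow(C)
  H <- if (q == 0) {
    matrix(stationary_distribution(C), n, n)
  } else {
    q * (diag(n) + walk_propagator(C, q))
  }
  if (is.null(start)) H else as.numeric(H[, start])
}
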