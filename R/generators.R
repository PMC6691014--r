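#' Graph generators for the two layers
#'
#' Convenience wrappers around igraph's samplers plus a spatial generator,
#' covering the experimental setups the model is usually exercised on:
#' Erdos-Renyi and Barabasi-Albert graphs for the large layer A, and a
#' Voronoi-adjacency spatial network for the small location layer B.
#'
#' @param n Number of nodes.
#' @param p Edge probability in `[0, 1]` (Erdos-Renyi).
#' @param seed Optional integer seed; when given the generator is
#'   deterministic and the caller's RNG state is preserved.
#' @return An undirected igraph.
#' @name generators
NULL

#' @rdname generators
#' @export
generate_er <- function(n, p, seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1) abort("n must be a positive count")
  if (!(p >= 0 && p <= 1)) abort("p must lie in [0, 1]")
  if (!is.null(seed)) withr::local_seed(seed)
  igraph::sample_gnp(n, p, directed = FALSE, loops = FALSE)
}

#' @rdname generators
#' @param m Edges attached by each new node (preferential attachment). With
#'   `m = 1` the result is a tree with `n - 1` edges.
#' @export
generate_ba <- function(n, m = 1, seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1) abort("n must be a positive count")
  if (!(m >= 1 && m < n)) abort("need 1 <= m < n")
  if (!is.null(seed)) withr::local_seed(seed)
  igraph::sample_pa(n, power = 1, m = m, directed = FALSE)
}

#' @rdname generators
#' @details
#' `generate_voronoi()` scatters `n` points uniformly on the unit square and
#' joins two points when their Voronoi cells share a boundary, i.e. when
#' they are Delaunay neighbors. The triangulation is computed by the
#' brute-force empty-circumcircle test over all point triples, which is
#' exact for points in general position and entirely adequate for the small
#' location networks the model assumes (the cost grows as `n^3` triples).
#' Degenerate samples (collinear triples, cocircular quadruples) are
#' resampled, with a message. Open boundaries: no periodic wrapping.
#' The result is always connected and planar, and carries the coordinates
#' as vertex attributes `x`, `y`.
#' @export
generate_voronoi <- function(n, seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 3) abort("n must be at least 3")
  if (!is.null(seed)) withr::local_seed(seed)
  for (attempt in seq_len(20)) {
    x <- runif(n)
    y <- runif(n)
    del <- delaunay_adjacency(x, y)
    if (del$degenerate) {
      inform("degenerate point configuration; resampling positions")
      next
    }
    g <- igraph::graph_from_adjacency_matrix(del$adjacency, mode = "undirected")
    if (!igraph::is_connected(g)) {
      inform("triangulation unexpectedly disconnected; resampling positions")
      next
    }
    igraph::V(g)$x <- x
    igraph::V(g)$y <- y
    return(g)
  }
  abort("failed to obtain a non-degenerate point configuration in 20 attempts")
}

# Delaunay neighbors via the empty-circumcircle criterion: the triangle
# (i, j, k) belongs to the triangulation iff no other point lies strictly
# inside its circumcircle. Near-cocircular ties are flagged as degenerate
# rather than resolved, and the caller resamples.
delaunay_adjacency <- function(x, y) {
  n <- length(x)
  adj <- matrix(FALSE, n, n)
  degenerate <- FALSE
  trips <- combn(n, 3)
  x2y2 <- x^2 + y^2
  for (c in seq_len(ncol(trips))) {
    i <- trips[1, c]; j <- trips[2, c]; k <- trips[3, c]
    d <- 2 * (x[i] * (y[j] - y[k]) + x[j] * (y[k] - y[i]) + x[k] * (y[i] - y[j]))
    if (abs(d) < 1e-12) { # collinear triple
      degenerate <- TRUE
      next
    }
    ux <- (x2y2[i] * (y[j] - y[k]) + x2y2[j] * (y[k] - y[i]) + x2y2[k] * (y[i] - y[j])) / d
    uy <- (x2y2[i] * (x[k] - x[j]) + x2y2[j] * (x[i] - x[k]) + x2y2[k] * (x[j] - x[i])) / d
    r2 <- (x[i] - ux)^2 + (y[i] - uy)^2
    dist2 <- (x - ux)^2 + (y - uy)^2
    dist2[c(i, j, k)] <- Inf
    m <- min(dist2)
    if (m > r2 * (1 - 1e-9) && m < r2 * (1 + 1e-9)) { # cocircular tie
      degenerate <- TRUE
      next
    }
    if (m > r2) {
      adj[i, j] <- adj[j, i] <- TRUE
      adj[i, k] <- adj[k, i] <- TRUE
      adj[j, k] <- adj[k, j] <- TRUE
    }
  }
  list(adjacency = adj, degenerate = degenerate)
}

#' @rdname generators
#' @export
generate_path <- function(n) {
  if (length(n) != 1 || is.na(n) || n < 2) abort("n must be at least 2")
  igraph::make_ring(n, circular = FALSE)
}
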