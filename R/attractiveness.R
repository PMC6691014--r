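#' Attractiveness vectors
#'
#' The attractiveness `f` of the location network B is a strictly positive
#' weight per node, normalized to sum to one so that it can be read as the
#' probability that a source node lands on each location, and as the bias of
#' the assignment walk. Weights may be supplied unnormalized (say, city
#' populations); `as_attractiveness()` rescales them.
#'
#' @param f Numeric vector of strictly positive weights, one per node of B.
#' @return A numeric vector of class `"attractiveness"` summing to 1.
#' @examples
#' f <- as_attractiveness(c(2, 1, 1))
#' sum(f)
#' @export
as_attractiveness <- function(f) {
  if (inherits(f, "attractiveness")) {
    return(f)
  }
  f <- as.numeric(f)
  if (length(f) < 1) {
    abort("attractiveness must have at least one entry")
  }
  if (any(!is.finite(f))) {
    abort("attractiveness entries must be finite")
  }
  if (any(f <= 0)) {
    abort(sprintf(
      "attractiveness entries must be strictly positive (offending index %d)",
      which(f <= 0)[1]
    ))
  }
  structure(f / sum(f), class = "attractiveness")
}

#' @export
print.attractiveness <- function(x, ...) {
  cat(sprintf("<attractiveness over %d location nodes>\n", length(x)))
  print(as.numeric(x), ...)
  invisible(x)
}

#' Sample attractiveness weights from a uniform distribution
#'
#' Draws raw weights i.i.d. from Uniform(low, high) and rescales them to sum
#' to one. With the default range (1, 100) the weights span two orders of
#' magnitude, a spread typical of, e.g., city populations served by a small
#' spatial network.
#'
#' @param n Number of location nodes.
#' @param low,high Bounds of the uniform distribution, `0 < low < high`.
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return An [as_attractiveness()] vector of length `n`.
#' @export
sample_attractiveness <- function(n, low = 1, high = 100, seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    abort("n must be a positive count")
  }
  if (!(low > 0 && high > low)) {
    abort("need 0 < low < high")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  as_attractiveness(runif(n, min = low, max = high))
}

#' Degree moments of a network
#'
#' First and second moments of the degree sequence. These are the only
#' features of network A that enter the mean-field description of the
#' assignment process.
#'
#' @param graph An undirected [igraph][igraph::igraph-package] graph.
#' @return A `"degree_moments"` object with fields `n_nodes`, `mean_k`,
#'   `mean_k2`.
#' @examples
#' g <- igraph::make_graph(~ 1 - 2 - 3)
#' degree_moments(g) # degrees 1, 2, 1
#' @export
degree_moments <- function(graph) {
  validate_graph(graph)
  k <- igraph::degree(graph)
  as_degree_moments(igraph::vcount(graph), mean(k), mean(k^2))
}

#' Construct degree moments directly
#'
#' Used when the moments come from somewhere other than a single realized
#' graph: an ensemble average, or a closed form such as the binomial moments
#' of an Erdos-Renyi model.
#'
#' @param n_nodes Number of nodes of network A.
#' @param mean_k,mean_k2 First and second moments of the degree distribution.
#' @return A `"degree_moments"` object.
#' @export
as_degree_moments <- function(n_nodes, mean_k, mean_k2) {
  if (n_nodes < 1) abort("n_nodes must be positive")
  if (mean_k < 0) abort("mean_k must be nonnegative")
  # Jensen: <k^2> >= <k>^2 for any real degree distribution
  if (mean_k2 < mean_k^2 - 1e-9) {
    abort("mean_k2 < mean_k^2 is not a valid pair of moments")
  }
  structure(
    list(n_nodes = as.integer(n_nodes), mean_k = mean_k, mean_k2 = mean_k2),
    class = "degree_moments"
  )
}

#' @export
print.degree_moments <- function(x, ...) {
  cat(sprintf(
    "<degree_moments> n = %d, <k> = %.6g, <k^2> = %.6g\n",
    x$n_nodes, x$mean_k, x$mean_k2
  ))
  invisible(x)
}
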