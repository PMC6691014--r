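#' Elementary draws of the assignment rule
#'
#' `choose_source()` picks one node uniformly from the pool of unassigned
#' A-nodes; `choose_target()` draws the source's location in B from the
#' attractiveness weights. Both use R's global RNG stream so that a run is
#' reproducible from a single seed.
#'
#' @param unassigned Integer vector of unassigned A-node indices.
#' @return A single node index.
#' @export
choose_source <- function(unassigned) {
  if (length(unassigned) == 0) {
    abort("no unassigned nodes remain: the assignment process is complete",
          class = "flexembed_complete")
  }
  unassigned[sample.int(length(unassigned), 1)]
}

#' @rdname choose_source
#' @param f Attractiveness weights.
#' @export
choose_target <- function(f) {
  f <- as_attractiveness(f)
  sample.int(length(f), 1, prob = f)
}

#' Attractiveness-weighted random walk with stopping
#'
#' From `start`, the walk first tests for a halt (probability `q`), and
#' otherwise hops from its current node `j` to neighbor `i` with
#' probability `f[i] B[i, j] / sum_l f[l] B[l, j]`. The stop test precedes
#' the first hop, so the walk returns `start` with probability at least
#' `q`, and with `q = 1` it never moves -- the fully local limit. The
#' `q -> 0` limit has no finite walk and is handled separately via
#' [stationary_distribution()].
#'
#' @param start 1-based start node in B.
#' @param graph Location network B; every node must have degree >= 1.
#' @param f Attractiveness weights.
#' @param q Stopping probability in `(0, 1]`.
#' @return The halting node index.
#' @export
stopped_walk <- function(start, graph, f, q) {
  if (!(length(q) == 1 && q > 0 && q <= 1)) {
    abort("q must lie in (0, 1]; for the q = 0 limit sample from stationary_distribution()")
  }
  f <- as_attractiveness(f)
  walk <- walk_tables(graph, f)
  walk_once(as.integer(start), q, walk$nbrs, walk$probs)
}

# Per-node neighbor lists and normalized neighbor-attractiveness weights.
walk_tables <- function(graph, f) {
  validate_graph(graph)
  n <- igraph::vcount(graph)
  if (length(f) != n) abort("length(f) must match the nodes of B")
  nbrs <- adjacency_list(graph)
  deg <- lengths(nbrs)
  if (any(deg == 0)) {
    abort(sprintf("node(s) %s of B are isolated; the walk is undefined there",
                  paste(which(deg == 0), collapse = ", ")))
  }
  probs <- lapply(nbrs, function(nb) {
    w <- as.numeric(f)[nb]
    w / sum(w)
  })
  list(nbrs = nbrs, probs = probs)
}

walk_once <- function(start, q, nbrs, probs) {
  cur <- start
  repeat {
    if (runif(1) < q) {
      return(cur)
    }
    nb <- nbrs[[cur]]
    cur <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1, prob = probs[[cur]])]
  }
}

adjacency_list <- function(graph) {
  n <- igraph::vcount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  from <- c(el[, 1], el[, 2])
  to <- c(el[, 2], el[, 1])
  ord <- order(from)
  unname(lapply(
    split(to[ord], factor(from[ord], levels = seq_len(n))),
    as.integer
  ))
}

#' Run one embedding of network A into network B
#'
#' Repeats the assignment rule until every A-node has a location: choose an
#' unassigned source uniformly, place it on a target location drawn from
#' the attractiveness weights, then place each currently unassigned
#' neighbor of the source at the halting node of an independent stopped
#' walk launched from the target (`q = 1`: the target itself; `q = 0`
#' limit: a draw from the stationary distribution of the weighted walk).
#' Neighbors placed in a step do not recruit their own neighborhoods; one
#' step is one source selection.
#'
#' @param graph_a Network A (large layer), undirected igraph.
#' @param graph_b Location network B, undirected igraph.
#' @param f Attractiveness weights on B.
#' @param q Stopping probability in `[0, 1]`, `0` meaning the limit.
#' @param seed Optional integer seed (caller's RNG state preserved).
#' @param trace Record the empirical moment trace of the unassigned pool
#'   (pool size and the moments of unassigned/assigned neighbor counts)
#'   before every source selection, plus a terminal row with `eta = 0`.
#' @return An `"embedding_realization"`: list with `assignment` (length
#'   `N_A`, values in `1..N_B`), `phi` (realized populations), `gamma`
#'   (symmetric `N_B x N_B` integer matrix of embedded edge weights,
#'   diagonal = within-location edges), `n_steps`, `q`, `seed`, and
#'   `trace` (tibble or `NULL`).
#' @export
run_embedding <- function(graph_a, graph_b, f, q, seed = NULL, trace = FALSE) {
  validate_graph(graph_a)
  validate_graph(graph_b)
  f <- as_attractiveness(f)
  if (!(length(q) == 1 && q >= 0 && q <= 1)) abort("q must lie in [0, 1]")
  n_a <- igraph::vcount(graph_a)
  n_b <- igraph::vcount(graph_b)
  if (length(f) != n_b) abort("length(f) must match the nodes of B")
  if (n_a <= n_b) {
    warn("network A is not larger than network B; the model premise is N_A > N_B")
  }
  if (!is.null(seed)) withr::local_seed(seed)

  adj_a <- adjacency_list(graph_a)
  walk <- NULL
  v0 <- NULL
  if (q > 0 && q < 1) {
    walk <- walk_tables(graph_b, f)
  } else if (q == 0) {
    v0 <- stationary_distribution(transition_matrix(graph_b, f))
  }
  fnum <- as.numeric(f)

  assignment <- rep(NA_integer_, n_a)
  pool <- seq_len(n_a)
  pos <- seq_len(n_a)
  npool <- n_a
  do_trace <- isTRUE(trace)
  if (do_trace) {
    ku <- igraph::degree(graph_a)
    ka <- integer(n_a)
    trace_rows <- vector("list", n_a + 1L)
  }
  take <- function(node, loc) {
    # swap-removal from the pool keeps source draws O(1)
    p <- pos[node]
    last <- pool[npool]
    pool[p] <<- last
    pos[last] <<- p
    npool <<- npool - 1L
    assignment[node] <<- loc
    if (do_trace) {
      nb <- adj_a[[node]]
      if (length(nb) > 0) {
        ku[nb] <<- ku[nb] - 1L
        ka[nb] <<- ka[nb] + 1L
      }
    }
  }

  steps <- 0L
  while (npool > 0) {
    if (do_trace) {
      live <- pool[seq_len(npool)]
      kuv <- ku[live]
      trace_rows[[steps + 1L]] <- c(steps, npool, mean(kuv), mean(kuv^2), mean(ka[live]))
    }
    steps <- steps + 1L
    src <- pool[sample.int(npool, 1)]
    tgt <- sample.int(n_b, 1, prob = fnum)
    nb <- adj_a[[src]]
    un <- nb[is.na(assignment[nb])]
    take(src, tgt)
    if (length(un) > 0) {
      if (q == 1) {
        for (x in un) take(x, tgt)
      } else if (q == 0) {
        for (x in un) take(x, sample.int(n_b, 1, prob = v0))
      } else {
        for (x in un) take(x, walk_once(tgt, q, walk$nbrs, walk$probs))
      }
    }
  }

  phi <- tabulate(assignment, nbins = n_b)
  gamma <- embedded_adjacency(graph_a, assignment, n_b)

  trace_tbl <- NULL
  if (do_trace) {
    trace_rows[[steps + 1L]] <- c(steps, 0, 0, 0, 0)
    tm <- do.call(rbind, trace_rows[!vapply(trace_rows, is.null, TRUE)])
    colnames(tm) <- c("t", "eta", "k1", "k2", "kd")
    trace_tbl <- as_tibble(as.data.frame(tm))
  }

  structure(
    list(
      assignment = assignment,
      phi = phi,
      gamma = gamma,
      n_steps = steps,
      q = q,
      seed = seed,
      n_a = n_a,
      n_b = n_b,
      n_edges_a = igraph::ecount(graph_a),
      trace = trace_tbl
    ),
    class = "embedding_realization"
  )
}

# Weighted embedded adjacency from a completed assignment: entry (i, j)
# counts A-edges between the groups mapped to locations i and j, each edge
# once; the diagonal holds within-location edge counts.
embedded_adjacency <- function(graph_a, assignment, n_b) {
  el <- igraph::as_edgelist(graph_a, names = FALSE)
  if (nrow(el) == 0) {
    return(matrix(0L, n_b, n_b))
  }
  li <- assignment[el[, 1]]
  lj <- assignment[el[, 2]]
  lo <- pmin(li, lj)
  hi <- pmax(li, lj)
  upper <- matrix(tabulate((hi - 1L) * n_b + lo, nbins = n_b * n_b), n_b, n_b)
  gamma <- upper + t(upper)
  diag(gamma) <- diag(upper)
  gamma
}

#' @export
print.embedding_realization <- function(x, ...) {
  cat(sprintf(
    "<embedding_realization> N_A = %d -> N_B = %d, q = %g, %d steps, |E_A| = %d\n",
    x$n_a, x$n_b, x$q, x$n_steps, x$n_edges_a
  ))
  invisible(x)
}
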