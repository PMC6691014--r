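#' Validate a simple undirected graph
#'
#' Both layers of the model are simple undirected unweighted graphs: no
#' self-loops, no multi-edges. Errors with an informative message otherwise.
#'
#' @param graph An [igraph][igraph::igraph-package] object.
#' @return `graph`, invisibly.
#' @export
validate_graph <- function(graph) {
  if (!igraph::is_igraph(graph)) {
    abort("expected an igraph object")
  }
  if (igraph::is_directed(graph)) {
    abort("graph must be undirected")
  }
  if (igraph::ecount(graph) > 0) {
    if (any(igraph::which_loop(graph))) {
      abort("graph must not contain self-loops")
    }
    if (any(igraph::which_multiple(graph))) {
      abort("graph must not contain multi-edges")
    }
  }
  invisible(graph)
}

#' Read an undirected graph from a plain-text edge list
#'
#' One edge per line as two whitespace-separated integers, 0-based node
#' indices; lines starting with `#` are comments. `(u, v)` and `(v, u)` are
#' the same edge and duplicate lines collapse to one edge. Files written by
#' [write_edge_list()] carry an `# n_nodes:` header comment which supplies
#' the node count when `n_nodes` is not given; otherwise the count defaults
#' to the largest index plus one.
#'
#' @param path Path to the edge-list file.
#' @param n_nodes Optional node count (must exceed every index in the file).
#' @return An undirected igraph with nodes `1..n_nodes` (file indices are
#'   0-based; in-memory indices are 1-based, the R convention).
#' @export
read_edge_list <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  header_n <- grep("^#\\s*n_nodes:\\s*[0-9]+", lines, value = TRUE)
  if (is.null(n_nodes) && length(header_n) > 0) {
    n_nodes <- as.integer(sub("^#\\s*n_nodes:\\s*([0-9]+).*$", "\\1", header_n[1]))
  }
  data_idx <- which(!grepl("^\\s*(#.*)?$", lines))
  ends <- matrix(integer(0), ncol = 2)
  if (length(data_idx) > 0) {
    toks <- strsplit(trimws(lines[data_idx]), "\\s+")
    bad <- which(lengths(toks) != 2)
    if (length(bad) > 0) {
      abort(sprintf("line %d: expected two integers", data_idx[bad[1]]))
    }
    u <- suppressWarnings(as.integer(vapply(toks, `[`, "", 1)))
    v <- suppressWarnings(as.integer(vapply(toks, `[`, "", 2)))
    if (anyNA(u) || anyNA(v)) {
      abort(sprintf(
        "line %d: could not parse integer node indices",
        data_idx[which(is.na(u) | is.na(v))[1]]
      ))
    }
    if (any(u < 0) || any(v < 0)) {
      abort(sprintf("line %d: negative node index", data_idx[which(u < 0 | v < 0)[1]]))
    }
    loops <- which(u == v)
    if (length(loops) > 0) {
      abort(sprintf("line %d: self-loop (%d %d) is not allowed",
                    data_idx[loops[1]], u[loops[1]], v[loops[1]]))
    }
    ends <- cbind(pmin(u, v), pmax(u, v))
    ends <- unique(ends)
  }
  max_idx <- if (nrow(ends) > 0) max(ends) else -1L
  if (is.null(n_nodes)) {
    n_nodes <- max_idx + 1L
  } else if (max_idx >= n_nodes) {
    abort(sprintf("node index %d out of range for n_nodes = %d", max_idx, n_nodes))
  }
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (nrow(ends) > 0) {
    g <- igraph::add_edges(g, as.vector(t(ends + 1L)))
  }
  validate_graph(g)
}

#' Write an undirected graph as a plain-text edge list
#'
#' Inverse of [read_edge_list()]: 0-based indices, one edge per line, plus
#' header comments recording the node count so isolated trailing nodes
#' survive a round trip.
#'
#' @param graph An undirected igraph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  validate_graph(graph)
  el <- igraph::as_edgelist(graph, names = FALSE) - 1L
  lines <- c(
    "# undirected edge list, 0-based node indices",
    sprintf("# n_nodes: %d", igraph::vcount(graph))
  )
  if (nrow(el) > 0) {
    lines <- c(lines, sprintf("%d %d", el[, 1], el[, 2]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write node attribute tables
#'
#' Node attributes (attractiveness, optional planar coordinates) travel as a
#' CSV with header `node,f[,x,y]` and 0-based node indices covering
#' `0..n-1`.
#'
#' @param path CSV file path.
#' @return For `read_node_attributes()`, a tibble with columns `node`
#'   (1-based in memory), `f`, and `x`, `y` when present.
#' @export
read_node_attributes <- function(path) {
  df <- read.csv(path)
  if (!all(c("node", "f") %in% names(df))) {
    abort("node attribute CSV must have columns 'node' and 'f'")
  }
  df <- df[order(df$node), , drop = FALSE]
  if (!identical(as.integer(df$node), seq_len(nrow(df)) - 1L)) {
    abort("node attribute CSV must cover 0-based contiguous indices 0..n-1")
  }
  df$node <- df$node + 1L
  as_tibble(df)
}

#' @rdname read_node_attributes
#' @param f Attractiveness weights (normalized on write).
#' @param positions Optional two-column matrix or data frame of coordinates.
#' @export
write_node_attributes <- function(f, path, positions = NULL) {
  f <- as_attractiveness(f)
  df <- data.frame(node = seq_along(f) - 1L, f = as.numeric(f))
  if (!is.null(positions)) {
    positions <- as.data.frame(positions)
    if (nrow(positions) != length(f) || ncol(positions) < 2) {
      abort("positions must have one (x, y) row per node")
    }
    df$x <- positions[[1]]
    df$y <- positions[[2]]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
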