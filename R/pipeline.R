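#' Run configurations
#'
#' A run configuration drives the whole simulation-versus-theory workflow:
#' how to obtain networks A and B and the attractiveness (generator
#' parameters or file paths), which stopping probabilities to scan, the
#' ensemble size, the base seed, and the integrator step. Configurations
#' are plain lists, readable from YAML. Defaults mirror the reference
#' experiment: A from an Erdos-Renyi model with `n = 1000, p = 0.01`
#' regenerated per realization, a 50-node Voronoi location network,
#' attractiveness from Uniform(1, 100) rescaled, and 1000 realizations.
#'
#' @param path Path to a YAML configuration file.
#' @param overrides Named list merged over the file values.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- fix_yaml_n_keys(yaml::read_yaml(path))
  cfg[names(overrides)] <- overrides
  validate_run_config(cfg)
}

# YAML 1.1 parses an unquoted key `n` as the boolean FALSE; map it back,
# since `n` is the node-count key of every generator spec.
fix_yaml_n_keys <- function(x) {
  if (!is.list(x)) {
    return(x)
  }
  nm <- names(x)
  if (!is.null(nm)) {
    names(x)[nm == "FALSE"] <- "n"
  }
  lapply(x, fix_yaml_n_keys)
}

#' @rdname read_run_config
#' @param config A configuration list.
#' @export
validate_run_config <- function(config) {
  defaults <- list(
    network_a = list(generator = "er", n = 1000L, p = 0.01),
    network_b = list(generator = "voronoi", n = 50L),
    attractiveness = list(low = 1, high = 100),
    q = c(0, 0.5, 1),
    n_realizations = 1000L,
    seed = 1L,
    ode_step = 0.1,
    out_dir = NULL
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  q <- as.numeric(unlist(config$q))
  if (any(q < 0 | q > 1)) abort("q values must lie in [0, 1]")
  config$q <- q
  if (config$n_realizations < 1) abort("n_realizations must be >= 1")
  for (k in c("network_a", "network_b", "attractiveness")) {
    p <- config[[k]]$path
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("%s: path '%s' does not exist", k, p))
    }
  }
  config
}

config_graph <- function(spec, seed, role) {
  if (!is.null(spec$path)) {
    return(read_edge_list(spec$path, n_nodes = spec$n))
  }
  gen <- spec$generator %||% abort(sprintf("%s: need a generator or a path", role))
  switch(gen,
    er = generate_er(spec$n, spec$p, seed = seed),
    ba = generate_ba(spec$n, spec$m %||% 1, seed = seed),
    voronoi = generate_voronoi(spec$n, seed = seed),
    path = generate_path(spec$n),
    abort(sprintf("%s: unknown generator '%s'", role, gen))
  )
}

config_attractiveness <- function(spec, n_b, seed) {
  if (!is.null(spec$path)) {
    return(as_attractiveness(read_node_attributes(spec$path)$f))
  }
  sample_attractiveness(n_b, low = spec$low %||% 1, high = spec$high %||% 100, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full simulation-versus-theory pipeline
#'
#' For each requested `q`: simulate the ensemble (regenerating network A
#' per realization when A comes from a generator), integrate the moment
#' equations once on the (ensemble-averaged) degree moments, build the
#' spectral objects once, assemble the analytic prediction, and tabulate
#' simulation-versus-theory z-scores. With an output directory set, all
#' artifacts are written there: the configuration echo, network B and the
#' attractiveness table, per-q comparison tables and predictions as CSV,
#' and a JSON summary. Fully deterministic under a fixed base seed (stage
#' seeds are derived from it by fixed offsets, per-realization seeds by
#' index).
#'
#' @param config A configuration list (see [read_run_config()]).
#' @param out_dir Output directory; overrides `config$out_dir`. `NULL`
#'   writes nothing.
#' @param verbose Emit progress messages.
#' @return A list with `comparisons` (named by q), `predictions`,
#'   `ensembles`, `summaries`, `config`, and `report` (the glance table).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  base_seed <- as.integer(config$seed)
  say <- function(...) if (isTRUE(verbose)) inform(sprintf(...))

  graph_b <- config_graph(config$network_b, seed = base_seed + 1L, role = "network_b")
  n_b <- igraph::vcount(graph_b)
  f <- config_attractiveness(config$attractiveness, n_b, seed = base_seed + 2L)
  regenerate_a <- is.null(config$network_a$path)
  graph_a <- if (regenerate_a) NULL else {
    config_graph(config$network_a, seed = base_seed + 3L, role = "network_a")
  }
  a_generator <- if (regenerate_a) {
    function(seed) config_graph(config$network_a, seed = seed, role = "network_a")
  } else {
    NULL
  }

  comparisons <- list()
  predictions <- list()
  ensembles <- list()
  summaries_by_q <- list()
  for (k in seq_along(config$q)) {
    q <- config$q[k]
    key <- format(q)
    say("q = %s: simulating %d realizations", key, config$n_realizations)
    ens <- run_ensemble(
      graph_a, graph_b, f, q,
      n_realizations = config$n_realizations,
      seed = base_seed + 1000L * k,
      a_generator = a_generator
    )
    say("q = %s: integrating moment equations and predicting", key)
    smry <- moment_summaries(integrate_moments(ens$moments, step = config$ode_step))
    pred <- embedding_prediction(smry, graph_b, f, q)
    comparisons[[key]] <- compare_tables(ens, pred)
    predictions[[key]] <- pred
    ensembles[[key]] <- ens
    summaries_by_q[[key]] <- smry
  }
  report <- purrr::map_dfr(comparisons, glance)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(
      c(config, list(rng_kind = RNGkind()[1], package_version = as.character(utils::packageVersion("flexembed")))),
      file.path(out_dir, "config.yaml")
    )
    write_edge_list(graph_b, file.path(out_dir, "network_b.edges"))
    pos <- if (!is.null(igraph::vertex_attr(graph_b, "x"))) {
      cbind(igraph::V(graph_b)$x, igraph::V(graph_b)$y)
    } else {
      NULL
    }
    write_node_attributes(f, file.path(out_dir, "attractiveness.csv"), positions = pos)
    for (key in names(comparisons)) {
      tag <- gsub("[^0-9a-zA-Z.]", "_", key)
      cmp <- comparisons[[key]]
      write.csv(cmp$phi, file.path(out_dir, sprintf("compare_phi_q%s.csv", tag)), row.names = FALSE)
      write.csv(cmp$gamma, file.path(out_dir, sprintf("compare_gamma_q%s.csv", tag)), row.names = FALSE)
      write_prediction_csv(predictions[[key]], out_dir, tag)
    }
    jsonlite::write_json(
      list(
        report = report,
        summaries = lapply(summaries_by_q, unclass),
        seed = base_seed
      ),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  list(
    comparisons = comparisons, predictions = predictions, ensembles = ensembles,
    summaries = summaries_by_q, config = config, report = report
  )
}

write_prediction_csv <- function(pred, out_dir, tag) {
  write.csv(
    data.frame(node = seq_along(pred$phi_mean) - 1L, predicted_phi = pred$phi_mean),
    file.path(out_dir, sprintf("predicted_phi_q%s.csv", tag)),
    row.names = FALSE
  )
  gm <- pred$gamma_mean
  idx <- which(upper.tri(gm, diag = TRUE), arr.ind = TRUE)
  write.csv(
    data.frame(
      i = idx[, 1] - 1L, j = idx[, 2] - 1L,
      predicted_weight = gm[idx]
    ),
    file.path(out_dir, sprintf("predicted_gamma_q%s.csv", tag)),
    row.names = FALSE
  )
}

#' Export one realization's artifacts
#'
#' Writes the assignment map, realized populations, and embedded weighted
#' edge list (including diagonal terms) as CSV, plus a JSON sidecar with
#' run metadata -- enough to replay or diff a run.
#'
#' @param realization An [run_embedding()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `dir`, invisibly.
#' @export
write_realization <- function(realization, dir, prefix = "run") {
  if (!inherits(realization, "embedding_realization")) {
    abort("expected an embedding_realization")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(
    data.frame(
      a_node = seq_along(realization$assignment) - 1L,
      b_node = realization$assignment - 1L
    ),
    file.path(dir, paste0(prefix, "_assignment.csv")),
    row.names = FALSE
  )
  write.csv(
    data.frame(node = seq_along(realization$phi) - 1L, phi = realization$phi),
    file.path(dir, paste0(prefix, "_phi.csv")),
    row.names = FALSE
  )
  gm <- realization$gamma
  idx <- which(upper.tri(gm, diag = TRUE) & gm > 0, arr.ind = TRUE)
  write.csv(
    data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L, weight = gm[idx]),
    file.path(dir, paste0(prefix, "_gamma.csv")),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      q = realization$q, seed = realization$seed, n_a = realization$n_a,
      n_b = realization$n_b, n_steps = realization$n_steps,
      n_edges_a = realization$n_edges_a
    ),
    file.path(dir, paste0(prefix, "_meta.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
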