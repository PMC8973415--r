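as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency * 1, mode = "undirected",
                                      diag = FALSE)
}

#' Binary graph from an adjacency matrix
#'
#' Wraps a symmetric logical/0-1 adjacency matrix (zero diagonal) in the
#' container used by the graph-metric functions; normally produced by
#' [proportional_threshold()], but useful directly for reference graphs.
#'
#' @param adj Symmetric square matrix, zero diagonal.
#' @param threshold Proportional threshold this graph came from, if any.
#' @param region_ids Optional node ids.
#' @return An object of class `binary_graph`.
#' @export
binary_graph <- function(adj, threshold = NA_real_, region_ids = NULL) {
  adj <- matrix(as.logical(adj), nrow(adj))
  stopifnot(isSymmetric(adj * 1), !any(diag(adj)))
  structure(list(adjacency = adj, threshold = threshold,
                 region_ids = region_ids %||% seq_len(nrow(adj))),
            class = "binary_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average clustering coefficient and characteristic path length
#'
#' `cp` is the mean Watts-Strogatz local clustering coefficient over all
#' nodes, with nodes of degree < 2 contributing 0. `lp` is the mean shortest
#' path length over all unordered node pairs that are connected; when the
#' graph is disconnected, unreachable pairs are excluded from the mean and
#' counted in `n_unreachable` (this keeps `lp` finite for sparse networks).
#' An edgeless graph has `cp = 0` and undefined `lp`.
#'
#' @param graph A [proportional_threshold()] result (`binary_graph`).
#' @return A list with `cp`, `lp`, `n_unreachable` (unordered pairs).
#' @export
clustering_and_path <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0L) {
    return(list(cp = 0, lp = NA_real_, n_unreachable = n * (n - 1) / 2))
  }
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0   # degree-1 nodes
  dmat <- igraph::distances(g)
  dv <- dmat[upper.tri(dmat)]
  reach <- is.finite(dv)
  list(cp = mean(cc),
       lp = if (any(reach)) mean(dv[reach]) else NA_real_,
       n_unreachable = sum(!reach))
}

#' Global efficiency
#'
#' `E_glob = (1/(n(n-1))) * sum_{i != j} 1/d_ij`, with `1/d_ij = 0` for
#' unreachable pairs. Lies in \[0, 1\]; 1 for a complete graph.
#'
#' @param graph A `binary_graph`.
#' @return Single numeric in \[0, 1\].
#' @export
global_efficiency <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  n <- nrow(graph$adjacency)
  if (n < 2L) {
    warning("global efficiency of a single-node graph is 0", call. = FALSE)
    return(0)
  }
  dmat <- igraph::distances(as_igraph(graph))
  inv <- 1 / dmat
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by each
#' node's neighbours; nodes with fewer than 2 neighbours contribute 0.
#'
#' @param graph A `binary_graph`.
#' @return Single numeric in \[0, 1\].
#' @export
local_efficiency <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  adj <- graph$adjacency
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ])
    if (length(nb) < 2L) return(0)
    sub <- binary_graph(adj[nb, nb, drop = FALSE])
    global_efficiency(sub)
  }, numeric(1))
  mean(vals)
}

#' Null-model configuration
#'
#' Settings for the degree-preserving random reference ensemble used to
#' normalise clustering and path length: `n_random` Maslov-Sneppen rewired
#' graphs, each produced by `n_swaps_per_edge * |E|` attempted double-edge
#' swaps, from a fixed seed.
#'
#' @param n_random Number of random reference networks (default 100).
#' @param n_swaps_per_edge Attempted swaps per edge (default 10).
#' @param seed Integer seed.
#' @return An object of class `null_model_config`.
#' @export
null_model_config <- function(n_random = 100L, n_swaps_per_edge = 10L,
                              seed = 1L) {
  stopifnot(n_random >= 0L, n_swaps_per_edge >= 1L)
  structure(list(n_random = as.integer(n_random),
                 n_swaps_per_edge = as.integer(n_swaps_per_edge),
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' Degree-preserving random reference ensemble
#'
#' Generates `cfg$n_random` rewired versions of the graph by Maslov-Sneppen
#' double-edge swaps (exactly preserving every node's degree) and returns the
#' ensemble means of the clustering coefficient and characteristic path
#' length, `crand` and `lrand`. Fully reproducible given `cfg$seed`.
#'
#' @param graph A `binary_graph` with at least 2 edges.
#' @param cfg A [null_model_config()].
#' @return A list with `crand`, `lrand`, `n_random`.
#' @export
random_reference_ensemble <- function(graph, cfg = null_model_config()) {
  stopifnot(inherits(graph, "binary_graph"),
            inherits(cfg, "null_model_config"))
  if (sum(graph$adjacency) / 2 < 2) {
    warning("graph has < 2 edges: null ensemble degenerates to the input",
            call. = FALSE)
    cl <- clustering_and_path(graph)
    return(list(crand = cl$cp, lrand = cl$lp, n_random = cfg$n_random))
  }
  nulls <- random_reference_graphs(graph, cfg)
  cls <- lapply(nulls, clustering_and_path)
  list(crand = mean(vapply(cls, `[[`, numeric(1), "cp")),
       lrand = mean(vapply(cls, `[[`, numeric(1), "lp"), na.rm = TRUE),
       n_random = cfg$n_random)
}

#' Degree-preserving rewired reference graphs
#'
#' The raw Maslov-Sneppen null ensemble behind
#' [random_reference_ensemble()]: each reference graph is produced by
#' `n_swaps_per_edge * |E|` attempted double-edge swaps and has exactly the
#' input's degree sequence.
#'
#' @param graph A `binary_graph`.
#' @param cfg A [null_model_config()].
#' @return A list of `cfg$n_random` `binary_graph` objects.
#' @export
random_reference_graphs <- function(graph, cfg = null_model_config()) {
  stopifnot(inherits(graph, "binary_graph"),
            inherits(cfg, "null_model_config"))
  g <- as_igraph(graph)
  niter <- cfg$n_swaps_per_edge * igraph::ecount(g)
  withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_random), function(i) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
      binary_graph(igraph::as_adjacency_matrix(gr, sparse = FALSE) > 0,
                   threshold = graph$threshold,
                   region_ids = graph$region_ids)
    })
  })
}

#' Small-world indices
#'
#' `gamma = cp/crand`, `lambda = lp/lrand`, `s = gamma/lambda`. A network is
#' small-world when `gamma > 1`, `lambda` is near 1, hence `s > 1`.
#'
#' @param cp,lp Clustering coefficient and path length of the target network.
#' @param crand,lrand Ensemble means of the matched random networks.
#' @return A list with `gamma`, `lambda`, `s`.
#' @export
small_world_metrics <- function(cp, lp, crand, lrand) {
  if (!is.na(crand) && crand == 0) {
    warning("crand = 0: gamma undefined", call. = FALSE)
    return(list(gamma = NA_real_, lambda = lp / lrand, s = NA_real_))
  }
  gamma <- cp / crand
  lambda <- lp / lrand
  list(gamma = gamma, lambda = lambda, s = gamma / lambda)
}

#' Graph metrics across proportional thresholds
#'
#' Thresholds one subject's connectivity matrix at each `k`, and for every
#' resulting binary graph computes the full metric set: `cp`, `lp`,
#' `gamma = cp/crand`, `lambda = lp/lrand`, `s = gamma/lambda`, global and
#' local efficiency. The random-network normalisation uses a fresh
#' degree-preserving ensemble per threshold, seeded from `cfg`.
#'
#' @param conn A [pearson_connectivity()] result.
#' @param thresholds Sorted vector of proportional thresholds in (0, 1].
#'   Default `seq(0.05, 0.30, by = 0.05)`.
#' @param cfg A [null_model_config()]; `n_random = 0` skips the random
#'   ensemble (gamma, lambda, s become `NA`), useful when only the raw
#'   metrics are needed.
#' @param rank Edge-ranking rule passed to [proportional_threshold()].
#' @return A tibble of class `dbca_metrics` with one row per threshold and
#'   columns `k, n_nodes, n_edges, cp, lp, n_unreachable, crand, lrand,
#'   gamma, lambda, s, e_glob, e_loc`.
#' @export
metrics_over_thresholds <- function(conn,
                                    thresholds = seq(0.05, 0.30, by = 0.05),
                                    cfg = null_model_config(),
                                    rank = "signed") {
  stopifnot(inherits(conn, "connectivity_matrix"),
            !is.unsorted(thresholds), all(thresholds > 0 & thresholds <= 1))
  rows <- purrr::map(seq_along(thresholds), function(i) {
    k <- thresholds[i]
    bg <- proportional_threshold(conn, k, rank = rank)
    cl <- clustering_and_path(bg)
    if (cfg$n_random > 0L) {
      nul <- random_reference_ensemble(
        bg, null_model_config(cfg$n_random, cfg$n_swaps_per_edge,
                              seed = cfg$seed + i))
      sw <- small_world_metrics(cl$cp, cl$lp, nul$crand, nul$lrand)
    } else {
      nul <- list(crand = NA_real_, lrand = NA_real_)
      sw <- list(gamma = NA_real_, lambda = NA_real_, s = NA_real_)
    }
    tibble::tibble(k = k,
                   n_nodes = nrow(bg$adjacency),
                   n_edges = sum(bg$adjacency) / 2,
                   cp = cl$cp, lp = cl$lp, n_unreachable = cl$n_unreachable,
                   crand = nul$crand, lrand = nul$lrand,
                   gamma = sw$gamma, lambda = sw$lambda, s = sw$s,
                   e_glob = global_efficiency(bg),
                   e_loc = local_efficiency(bg))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("dbca_metrics", class(out))
  out
}
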