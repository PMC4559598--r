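as_igraph <- function(g) {
  adj <- if (inherits(g, "binary_graph")) g$adjacency else g
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

as_binary_graph <- function(g) {
  if (inherits(g, "binary_graph")) return(g)
  check_square_symmetric(g, what = "adjacency")
  structure(list(adjacency = (g != 0) * 1, n_nodes = nrow(g),
                 n_edges = sum(g != 0) / 2),
            class = "binary_graph")
}

#' Network sparsity (density)
#'
#' Fraction of possible edges present, `2E / (N(N-1))`.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @return Real in \[0, 1\].
#' @export
graph_sparsity <- function(g) {
  g <- as_binary_graph(g)
  if (g$n_nodes < 2L) stop("invalid graph: need at least 2 nodes",
                           call. = FALSE)
  2 * g$n_edges / (g$n_nodes * (g$n_nodes - 1))
}

#' Clustering coefficient
#'
#' Per node i with degree >= 2, the fraction of realized triangles among
#' its neighbor pairs; nodes with degree < 2 contribute 0. The network
#' value Cp is the mean over all N nodes.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @return List with `cp` (network mean) and `nodal` (per-node vector).
#' @export
clustering_coefficient <- function(g) {
  g <- as_binary_graph(g)
  if (g$n_nodes < 3L) stop("invalid graph: need at least 3 nodes",
                           call. = FALSE)
  nodal <- igraph::transitivity(as_igraph(g), type = "local",
                                isolates = "zero")
  list(cp = mean(nodal), nodal = nodal)
}

#' Characteristic path length
#'
#' Mean shortest-path length over connected unordered node pairs only;
#' disconnected pairs are excluded and the component census is reported
#' alongside so partial connectivity is never silent.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @return List with `lp`, `n_components`, `largest_component`.
#' @export
characteristic_path_length <- function(g) {
  g <- as_binary_graph(g)
  if (g$n_edges < 1L) stop("path length undefined: graph has no edges",
                           call. = FALSE)
  ig <- as_igraph(g)
  comp <- igraph::components(ig)
  list(lp = igraph::mean_distance(ig, directed = FALSE, unconnected = TRUE),
       n_components = comp$no,
       largest_component = max(comp$csize))
}

#' Degree assortativity
#'
#' Newman's degree-degree Pearson correlation over edges, each undirected
#' edge contributing both orientations. Undefined (NaN) for regular graphs,
#' where the endpoint-degree variance is zero.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @return Real in \[-1, 1\], or NaN when undefined.
#' @export
graph_assortativity <- function(g) {
  g <- as_binary_graph(g)
  if (g$n_edges < 2L) stop("assortativity undefined: need >= 2 edges",
                           call. = FALSE)
  igraph::assortativity_degree(as_igraph(g), directed = FALSE)
}

#' Nodal degree centrality
#'
#' Number of edges attached to each node (adjacency row sums).
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @return Integer vector of length N.
#' @export
degree_centrality <- function(g) {
  g <- as_binary_graph(g)
  as.integer(rowSums(g$adjacency))
}

#' Degree-preserving (Maslov-Sneppen) rewiring
#'
#' Randomizes a graph by repeated double-edge swaps that reject self-loops
#' and multi-edges, preserving every node's degree exactly. The number of
#' attempted swaps is `swaps_per_edge * E`. Complete graphs (which admit no
#' valid swap) are returned unchanged with a warning.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @param seed Integer seed.
#' @return A rewired `binary_graph` with identical degree sequence.
#' @export
maslov_sneppen_rewire <- function(g, swaps_per_edge = 10L, seed = 1L) {
  g <- as_binary_graph(g)
  if (g$n_edges < 2L) stop("rewiring needs at least 2 edges", call. = FALSE)
  n_possible <- g$n_nodes * (g$n_nodes - 1) / 2
  if (g$n_edges == n_possible) {
    warning("complete graph admits no degree-preserving swap; ",
            "returned unchanged", call. = FALSE)
    out <- g
    out$warning <- "no-valid-swap"
    return(out)
  }
  with_local_seed(seed, {
    ig <- igraph::rewire(as_igraph(g),
                         igraph::keeping_degseq(loops = FALSE,
                                                niter = swaps_per_edge *
                                                  g$n_edges))
    adj <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = FALSE))
    structure(list(adjacency = adj, n_nodes = g$n_nodes,
                   n_edges = g$n_edges),
              class = "binary_graph")
  })
}

#' Global topology of a binary graph
#'
#' All global metrics in one pass: sparsity S, clustering Cp, path length
#' Lp, assortativity alpha, and the component census.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @return Named list (class `global_metrics`).
#' @export
global_metrics <- function(g) {
  g <- as_binary_graph(g)
  cc <- clustering_coefficient(g)
  pl <- characteristic_path_length(g)
  structure(
    list(sparsity = graph_sparsity(g), cp = cc$cp, lp = pl$lp,
         assortativity = if (g$n_edges >= 2L) graph_assortativity(g)
                         else NaN,
         n_components = pl$n_components,
         largest_component = pl$largest_component),
    class = "global_metrics"
  )
}

#' Random-network-normalized topology
#'
#' Normalizes clustering, path length and assortativity against an ensemble
#' of degree-preserving rewired null networks: `gamma = Cp / <Cp_rand>`,
#' `lambda = Lp / <Lp_rand>`, small-worldness `sigma = gamma / lambda`, and
#' `alpha_z = (alpha - <alpha_rand>) / sd(alpha_rand)` with the sample
#' (n - 1) standard deviation. Null metrics are computed with this module's
#' own operations.
#'
#' @param g A `binary_graph` or adjacency matrix.
#' @param n_rand Ensemble size (default 100).
#' @param swaps_per_edge Attempted swaps per edge per null.
#' @param seed Integer seed (one per-null seed is derived per replicate).
#' @return List with `gamma`, `lambda`, `sigma`, `alpha_z` and the null
#'   ensemble summaries.
#' @export
normalized_metrics <- function(g, n_rand = 100L, swaps_per_edge = 10L,
                               seed = 1L) {
  g <- as_binary_graph(g)
  if (n_rand < 2L) stop("`n_rand` must be >= 2", call. = FALSE)
  real <- global_metrics(g)
  cp_r <- lp_r <- al_r <- numeric(n_rand)
  for (k in seq_len(n_rand)) {
    null <- maslov_sneppen_rewire(g, swaps_per_edge,
                                  seed = derive_seed(seed, k))
    cp_r[k] <- clustering_coefficient(null)$cp
    lp_r[k] <- characteristic_path_length(null)$lp
    al_r[k] <- graph_assortativity(null)
  }
  if (all(!is.finite(cp_r)) || all(!is.finite(lp_r))) {
    stop("normalization failure: degenerate null ensemble", call. = FALSE)
  }
  al_ok <- al_r[is.finite(al_r)]
  gamma <- real$cp / mean(cp_r)
  lambda <- real$lp / mean(lp_r)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       alpha_z = if (length(al_ok) >= 2L && is.finite(real$assortativity))
                   (real$assortativity - mean(al_ok)) / sd(al_ok)
                 else NaN,
       cp_rand_mean = mean(cp_r), lp_rand_mean = mean(lp_r),
       alpha_rand_mean = mean(al_ok), alpha_rand_sd = sd(al_ok),
       n_rand = n_rand)
}

#' Weighted-network topology
#'
#' Nodal strength (weighted degree), Onnela weighted clustering on weights
#' normalized by the maximum weight, and weighted characteristic path
#' length with edge length `1 / weight`, averaged over connected pairs.
#'
#' @param g A `weighted_graph` or symmetric nonnegative weight matrix.
#' @return List with `strength`, `cp_w` (and `nodal_cp_w`), `lp_w`.
#' @export
weighted_metrics <- function(g) {
  w <- if (inherits(g, "weighted_graph")) g$weights else g
  check_square_symmetric(w, what = "weight matrix")
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  n <- nrow(w)
  strength <- rowSums(w)
  k <- rowSums(w > 0)
  # Onnela clustering: geometric-mean triangle intensity on max-normalized
  # weights.
  wh <- if (max(w) > 0) (w / max(w))^(1 / 3) else w
  tri <- diag(wh %*% wh %*% wh)
  nodal_cp <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  finite <- d[upper.tri(d)]
  finite <- finite[is.finite(finite)]
  if (!length(finite)) stop("path length undefined: no connected pairs",
                            call. = FALSE)
  list(strength = strength, cp_w = mean(nodal_cp), nodal_cp_w = nodal_cp,
       lp_w = mean(finite))
}
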