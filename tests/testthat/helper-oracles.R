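# Brute-force graph oracles, independent of the package implementation
# (and of igraph): triangle enumeration, Floyd-Warshall, edge-endpoint
# Pearson, plus small random-graph generators for property tests.

oracle_degree <- function(adj) as.integer(rowSums(adj))

# Per-node clustering by explicit enumeration of neighbor pairs.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0L
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] == 1) links <- links + 1L
      }
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# Mean shortest path over connected pairs via Floyd-Warshall.
oracle_path_length <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  up <- d[upper.tri(d)]
  mean(up[is.finite(up)])
}

# Newman assortativity as the Pearson correlation of endpoint degrees over
# both orientations of every edge.
oracle_assortativity <- function(adj) {
  deg <- rowSums(adj)
  idx <- which(adj == 1, arr.ind = TRUE) # both orientations
  suppressWarnings(cor(deg[idx[, 1]], deg[idx[, 2]]))
}

# Erdos-Renyi adjacency matrix.
random_adjacency <- function(n, p) {
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  on <- up[runif(length(up)) < p]
  m[on] <- 1
  m + t(m)
}

# Random connected graph by rejection.
random_connected_adjacency <- function(n, p) {
  repeat {
    adj <- random_adjacency(n, p)
    d <- matrix(Inf, n, n)
    d[adj == 1] <- 1
    diag(d) <- 0
    for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
    if (all(is.finite(d))) return(adj)
  }
}

# Ring lattice where each node connects to `k` nearest neighbors per side
# (Watts-Strogatz substrate).
ring_lattice <- function(n, k) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k)) {
      j <- ((i - 1 + s) %% n) + 1
      adj[i, j] <- 1
      adj[j, i] <- 1
    }
  }
  adj
}

# Tiny fast preset for pipeline-level tests.
tiny_preset <- function(seed = 42L) {
  default_preset(seed = seed, n_pairs = 6L, n_hubs = 2L)
}
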