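complete_graph <- function(n) {
  m <- matrix(1, n, n)
  diag(m) <- 0
  m
}

path_graph <- function(n) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- 1
  m
}

star_graph <- function(n_leaves) {
  m <- matrix(0, n_leaves + 1, n_leaves + 1)
  m[1, -1] <- m[-1, 1] <- 1
  m
}

test_that("sparsity counts edges against all possible pairs", {
  expect_equal(graph_sparsity(complete_graph(5)), 1)
  expect_equal(graph_sparsity(matrix(0, 5, 5)), 0)
  expect_equal(graph_sparsity(ring_lattice(6, 1)), 0.4) # 6 of 15 pairs
  g <- ring_lattice(6, 1)
  g[1, 4] <- g[4, 1] <- 1
  expect_gt(graph_sparsity(g), 0.4)
})

test_that("clustering matches closed forms and the triangle oracle", {
  expect_equal(clustering_coefficient(complete_graph(4))$cp, 1)
  expect_equal(clustering_coefficient(star_graph(4))$cp, 0)
  set.seed(21)
  for (rep in 1:20) {
    adj <- random_adjacency(sample(4:12, 1), runif(1, 0.2, 0.8))
    if (sum(adj) == 0) next
    cc <- clustering_coefficient(adj)
    expect_equal(cc$nodal, oracle_clustering(adj), tolerance = 1e-12)
    expect_equal(cc$cp, mean(oracle_clustering(adj)), tolerance = 1e-12)
  }
})

test_that("path length averages over connected pairs only", {
  expect_equal(characteristic_path_length(complete_graph(5))$lp, 1)
  expect_equal(characteristic_path_length(path_graph(4))$lp, 10 / 6,
               tolerance = 1e-12)
  two_k3 <- matrix(0, 6, 6)
  two_k3[1:3, 1:3] <- complete_graph(3)
  two_k3[4:6, 4:6] <- complete_graph(3)
  pl <- characteristic_path_length(two_k3)
  expect_equal(pl$lp, 1)
  expect_equal(pl$n_components, 2)
  expect_equal(pl$largest_component, 3)
  expect_error(characteristic_path_length(matrix(0, 4, 4)), "no edges")
})

test_that("assortativity matches the edge-endpoint Pearson oracle", {
  expect_equal(graph_assortativity(star_graph(3)), -1, tolerance = 1e-12)
  expect_true(is.nan(graph_assortativity(ring_lattice(6, 1))))
  expect_true(is.nan(graph_assortativity(complete_graph(5))))
  set.seed(22)
  checked <- 0
  while (checked < 20) {
    adj <- random_adjacency(sample(5:12, 1), runif(1, 0.25, 0.7))
    a <- oracle_assortativity(adj)
    if (sum(adj) / 2 < 2 || is.na(a)) next
    expect_equal(graph_assortativity(adj), a, tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("degree centrality is the adjacency row sum", {
  expect_equal(degree_centrality(star_graph(4)), c(4L, 1L, 1L, 1L, 1L))
  set.seed(23)
  adj <- random_adjacency(10, 0.4)
  deg <- degree_centrality(adj)
  expect_equal(deg, oracle_degree(adj))
  expect_equal(sum(deg), sum(adj)) # handshake: sum k = 2E
})

test_that("rewiring preserves the degree sequence", {
  set.seed(24)
  for (rep in 1:20) {
    adj <- random_connected_adjacency(sample(8:14, 1), runif(1, 0.25, 0.6))
    g <- maslov_sneppen_rewire(adj, swaps_per_edge = 10, seed = rep)
    expect_equal(sort(degree_centrality(g)),
                 sort(degree_centrality(adj)))
    expect_equal(degree_centrality(g), degree_centrality(adj))
  }
  expect_warning(k3 <- maslov_sneppen_rewire(complete_graph(3), seed = 1),
                 "no degree-preserving swap")
  expect_equal(k3$adjacency, complete_graph(3))
})

test_that("rewiring destroys lattice clustering", {
  lattice <- ring_lattice(20, 3)
  cp0 <- clustering_coefficient(lattice)$cp
  cps <- vapply(1:50, function(k) {
    clustering_coefficient(maslov_sneppen_rewire(lattice, 10, seed = k))$cp
  }, numeric(1))
  expect_lt(mean(cps), cp0)
})

test_that("small-world normalization behaves across graph families", {
  # ring lattice with mild rewiring: strongly clustered, sigma > 1
  lattice <- ring_lattice(30, 3)
  sw <- maslov_sneppen_rewire(lattice, swaps_per_edge = 1, seed = 5)
  nm <- normalized_metrics(sw, n_rand = 20, seed = 6)
  expect_gt(nm$sigma, 1)
  expect_equal(nm$sigma, nm$gamma / nm$lambda, tolerance = 1e-12)
})

test_that("metrics are invariant under node relabeling", {
  set.seed(25)
  adj <- random_connected_adjacency(10, 0.4)
  perm <- sample(10)
  padj <- adj[perm, perm]
  expect_equal(graph_sparsity(padj), graph_sparsity(adj))
  expect_equal(clustering_coefficient(padj)$cp,
               clustering_coefficient(adj)$cp, tolerance = 1e-12)
  expect_equal(characteristic_path_length(padj)$lp,
               characteristic_path_length(adj)$lp, tolerance = 1e-12)
  if (!is.nan(oracle_assortativity(adj))) {
    expect_equal(graph_assortativity(padj), graph_assortativity(adj),
                 tolerance = 1e-12)
  }
  expect_equal(sort(degree_centrality(padj)),
               sort(degree_centrality(adj)))
})

test_that("weighted metrics reduce to binary values at uniform weights", {
  set.seed(26)
  adj <- random_connected_adjacency(8, 0.5)
  wm <- weighted_metrics(adj * 0.5)
  expect_equal(wm$cp_w, clustering_coefficient(adj)$cp, tolerance = 1e-12)
  expect_equal(wm$lp_w, characteristic_path_length(adj)$lp / 0.5,
               tolerance = 1e-12)
  expect_equal(weighted_metrics(adj * 1)$strength,
               as.numeric(degree_centrality(adj)))
})

test_that("weighted clustering and paths match a hand-built oracle", {
  # 4-node weighted graph: edges 1-2 (0.8), 1-3 (0.4), 2-3 (0.2), 3-4 (1.0)
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.8
  w[1, 3] <- w[3, 1] <- 0.4
  w[2, 3] <- w[3, 2] <- 0.2
  w[3, 4] <- w[4, 3] <- 1.0
  wm <- weighted_metrics(w)
  # Onnela: normalized weights are w / 1.0; node 1 has one triangle of
  # intensity (0.8 * 0.4 * 0.2)^(1/3) and degree 2 ->
  # cp_1 = 2 * intensity / (k (k - 1)) = intensity
  int1 <- (0.8 * 0.4 * 0.2)^(1 / 3)
  expect_equal(wm$nodal_cp_w[1], int1, tolerance = 1e-12)
  expect_equal(wm$nodal_cp_w[4], 0)
  # Dijkstra with lengths 1/w: d(1,2) = 1.25, d(1,3) = 2.5,
  # d(2,3) = 1.25 + 2.5 = 3.75 beats 1/0.2 = 5; d(1,4) = 3.5,
  # d(2,4) = 4.75, d(3,4) = 1
  dists <- c(1.25, 2.5, 3.5, 3.75, 4.75, 1)
  expect_equal(wm$lp_w, mean(dists), tolerance = 1e-12)
  expect_equal(wm$strength, c(1.2, 1.0, 1.6, 1.0))
})
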