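test_that("parcellation has paired homologs across hemispheres", {
  parc <- generate_parcellation(45, seed = 1)
  expect_equal(nrow(parc), 90)
  expect_equal(sum(parc$hemisphere == "L"), 45)
  expect_equal(sum(parc$hemisphere == "R"), 45)
  expect_true(all(parc$volume > 0))
  # homolog mapping is symmetric and crosses hemispheres
  hm <- parc$homolog_id
  expect_equal(hm[hm + 1L], parc$region_id)
  expect_true(all(parc$hemisphere != parc$hemisphere[hm + 1L]))

  small <- generate_parcellation(2, seed = 1)
  expect_equal(small$homolog_id[small$region_id == 0], 2)
  expect_equal(small$homolog_id[small$region_id == 2], 0)

  expect_error(generate_parcellation(1, seed = 1), "n_pairs")
  expect_identical(generate_parcellation(3, seed = 7),
                   generate_parcellation(3, seed = 7))
})

test_that("structural truth hits the requested density with planted hubs", {
  parc <- generate_parcellation(45, seed = 2)
  truth <- generate_structural_truth(parc, density = 0.21, n_hubs = 6,
                                     homotopic_guarantee = TRUE, seed = 3)
  n <- 90
  e_target <- 0.21 * n * (n - 1) / 2
  expect_lte(abs(truth$n_edges - e_target), 1)
  adj <- (truth$weights > 0) * 1
  expect_equal(adj, t(adj))
  expect_equal(diag(adj), rep(0, n))
  # all homotopic pairs connected
  for (i in 0:44) expect_equal(adj[i + 1, i + 46], 1)
  # hub degrees at least twice the non-hub mean
  deg <- rowSums(adj)
  hubs <- truth$hub_nodes + 1
  expect_true(all(deg[hubs] >= 2 * mean(deg[-hubs])))
})

test_that("structural truth degenerate and infeasible cases", {
  parc <- generate_parcellation(3, seed = 1)
  full <- generate_structural_truth(parc, density = 1, n_hubs = 0, seed = 1)
  expect_equal(rowSums(full$weights > 0), rep(5, 6))
  expect_error(
    generate_structural_truth(parc, density = 1, n_hubs = 2, seed = 1),
    "infeasible"
  )
})

test_that("streamline counts are symmetric Poisson draws on the skeleton", {
  parc <- generate_parcellation(4, seed = 5)
  truth <- make_ground_truth(parc, density = 0.5, n_hubs = 0, seed = 5)
  counts <- simulate_streamline_counts(truth, parc, scale = 10, seed = 9)
  expect_equal(counts, t(counts))
  expect_equal(diag(counts), rep(0, 8))
  expect_true(all(counts[truth$structural_weights == 0] == 0))
  expect_error(simulate_streamline_counts(truth, parc, scale = 0), "scale")

  # Monte-Carlo oracle: normalized count (count / mean volume) matches
  # scale * weight in expectation, within 3 standard errors.
  n_draws <- 10000
  i <- which(truth$structural_weights > 0, arr.ind = TRUE)[1, ]
  vol <- parc$volume[match(0:7, parc$region_id)]
  vmean <- (vol[i[1]] + vol[i[2]]) / 2
  draws <- vapply(seq_len(n_draws), function(d) {
    simulate_streamline_counts(truth, parc, scale = 10,
                               seed = d)[i[1], i[2]] / vmean
  }, numeric(1))
  expected <- 10 * truth$structural_weights[i[1], i[2]]
  se <- sd(draws) / sqrt(n_draws)
  expect_lt(abs(mean(draws) - expected), 3 * se)
})

test_that("decoupled single-state generator yields independent regions", {
  parc <- generate_parcellation(5, seed = 11)
  truth <- make_ground_truth(parc, density = 0.3, n_hubs = 0, n_states = 1,
                             homotopic_boost = 0, coupling_gain = 0,
                             background = 0, seed = 11)
  ts <- simulate_bold(truth, parc, n_timepoints = 20000, seed = 12)
  r <- static_fc(ts)
  expect_lt(max(abs(r[upper.tri(r)])), 0.05)
})

test_that("homotopic boost raises homotopic over heterotopic correlation", {
  parc <- generate_parcellation(10, seed = 21)
  truth <- make_ground_truth(parc, density = 0.2, n_hubs = 2, seed = 21)
  ts <- simulate_bold(truth, parc, n_timepoints = 5000, seed = 22)
  r <- static_fc(ts)
  cats <- classify_edges(parc)
  ei <- attr(cats, "index")
  vals <- r[ei]
  expect_gt(mean(vals[cats == "homotopic"]),
            mean(vals[cats == "heterotopic"]))
})

test_that("structural coupling is monotone in the analytic correlations", {
  parc <- generate_parcellation(20, seed = 31)
  truth <- make_ground_truth(parc, density = 0.21, n_hubs = 4, seed = 31)
  w <- truth$structural_weights
  mc <- state_mean_correlation(truth)
  conn <- which(upper.tri(w) & w > 0)
  expect_gt(cor(w[conn], mc[conn], method = "spearman"), 0)
})

test_that("single-state temporal variability shrinks with window length", {
  parc <- generate_parcellation(6, seed = 41)
  truth <- make_ground_truth(parc, density = 0.4, n_hubs = 0, n_states = 1,
                             seed = 41)
  ts <- simulate_bold(truth, parc, n_timepoints = 3000, seed = 42)
  med_tvar <- function(len) {
    dfc <- sliding_window_dfc(ts, window_spec(len, 10))
    es <- temporal_edge_stats(dfc)
    median(es$variability[upper.tri(es$variability)])
  }
  v50 <- med_tvar(50)
  v300 <- med_tvar(300)
  # estimation noise only: var of windowed r scales like 1/(L - 3)
  expect_gt(v50, v300)
})

test_that("bold simulation is reproducible and returns the state path", {
  parc <- generate_parcellation(4, seed = 51)
  truth <- make_ground_truth(parc, density = 0.4, n_hubs = 0, seed = 51)
  a <- simulate_bold(truth, parc, n_timepoints = 500, seed = 7)
  b <- simulate_bold(truth, parc, n_timepoints = 500, seed = 7)
  expect_identical(a, b)
  expect_equal(length(a$states), 500)
  expect_true(all(a$states %in% seq_len(truth$n_states)))
  expect_error(simulate_bold(truth, parc, n_timepoints = 1), "n_timepoints")
})

test_that("state correlations are valid correlation matrices", {
  parc <- generate_parcellation(10, seed = 61)
  truth <- make_ground_truth(parc, density = 0.21, n_hubs = 2, seed = 61)
  for (ck in truth$state_correlations) {
    expect_equal(diag(ck), rep(1, 20))
    expect_equal(ck, t(ck))
    expect_gt(min(eigen(ck, symmetric = TRUE, only.values = TRUE)$values),
              0)
    expect_lte(max(abs(ck[upper.tri(ck)])), 1)
  }
})
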