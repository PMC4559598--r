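test_that("window count matches the closed form", {
  expect_equal(window_count(883, window_spec(155, 1)), 729L)
  expect_equal(window_count(155, window_spec(155, 7)), 1L)
  expect_equal(window_count(10, window_spec(4, 3)), 3L) # onsets 0, 3, 6
  expect_error(window_count(100, window_spec(155, 1)), "invalid window")
  # closed form on a grid
  for (tt in c(200, 883, 1000)) {
    for (len in c(50, 155)) {
      for (st in c(1, 5, 17)) {
        spec <- window_spec(len, st)
        onsets <- seq(0, tt - len, by = st)
        expect_equal(window_count(tt, spec), length(onsets))
      }
    }
  }
  expect_error(window_spec(2), "length")
  expect_error(window_spec(10, 0), "step")
})

test_that("100 s at TR 0.645 s is a 155-sample window", {
  expect_equal(window_spec_seconds(100, 0.645)$length, 155L)
  expect_equal(window_spec_seconds(50, 0.645)$length, 78L)
  expect_equal(window_spec_seconds(150, 0.645)$length, 233L)
})

test_that("sliding-window correlations match a brute-force oracle", {
  set.seed(1)
  x <- matrix(rnorm(6 * 3), 6, 3)
  dfc <- sliding_window_dfc(x, window_spec(4, 1))
  expect_equal(dfc$n_windows, 3L)
  for (t in 1:3) {
    seg <- x[t:(t + 3), ]
    for (i in 1:2) {
      for (j in (i + 1):3) {
        expect_equal(dfc$r[i, j, t], cor(seg[, i], seg[, j]),
                     tolerance = 1e-12)
        expect_equal(dfc$r[i, j, t], dfc$r[j, i, t])
      }
    }
  }
})

test_that("degenerate column patterns give unit correlations or errors", {
  base <- rnorm(20)
  x <- cbind(base, base, -base, rnorm(20))
  dfc <- sliding_window_dfc(x, window_spec(5, 5))
  expect_true(all(abs(dfc$r[1, 2, ] - 1) < 1e-12))
  expect_true(all(abs(dfc$r[1, 3, ] + 1) < 1e-12))
  xc <- cbind(rnorm(20), rep(1, 20))
  expect_error(sliding_window_dfc(xc, window_spec(5, 5)),
               "constant within window 1")
})

test_that("static connectivity equals full-length Pearson correlation", {
  set.seed(2)
  x <- matrix(rnorm(8 * 3), 8, 3)
  s <- static_fc(x)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(s[i, j], cor(x[, i], x[, j]), tolerance = 1e-12)
    }
  }
  # a full-length window reproduces the static matrix
  dfc <- sliding_window_dfc(x, window_spec(8, 1))
  expect_equal(dfc$r[, , 1], s, ignore_attr = TRUE)
  # relabeling consistency
  perm <- c(3, 1, 2)
  expect_equal(static_fc(x[, perm]), s[perm, perm], ignore_attr = TRUE)
})

test_that("fisher transform is atanh with clipping at the boundary", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(is.finite(fisher_z(1)))
  expect_error(fisher_z(1, clip = FALSE), "domain|atanh")
})

test_that("spatial similarity is a correlation over fisher-z edges", {
  set.seed(3)
  x <- matrix(rnorm(30 * 5), 30, 5)
  s <- static_fc(x)
  dfc <- sliding_window_dfc(x, window_spec(30, 1)) # the single window IS s
  expect_equal(spatial_similarity(s, dfc), 1, tolerance = 1e-12)
  neg <- dfc
  neg$r <- -dfc$r
  expect_equal(spatial_similarity(s, neg), -1, tolerance = 1e-12)
})

test_that("temporal edge statistics follow the mean/variance kernels", {
  # hand evaluation: series {0.2, 0.4, 0.6}
  r <- array(0, dim = c(2, 2, 3))
  r[1, 2, ] <- c(0.2, 0.4, 0.6)
  r[2, 1, ] <- c(0.2, 0.4, 0.6)
  dfc <- structure(list(r = r, onsets = 0:2, spec = window_spec(4, 1),
                        n_windows = 3L), class = "dfc_series")
  es <- temporal_edge_stats(dfc)
  expect_equal(es$strength[1, 2], 0.4, tolerance = 1e-12)
  expect_equal(es$variability[1, 2], 0.04, tolerance = 1e-12)
  # standard-deviation option is the square root
  expect_equal(temporal_edge_stats(dfc, "std")$variability[1, 2], 0.2,
               tolerance = 1e-12)
  # constant series
  rc <- array(0.5, dim = c(2, 2, 4))
  dfcc <- structure(list(r = rc, onsets = 0:3, spec = window_spec(4, 1),
                         n_windows = 4L), class = "dfc_series")
  esc <- temporal_edge_stats(dfcc)
  expect_equal(esc$strength[1, 2], 0.5)
  expect_equal(esc$variability[1, 2], 0)
  # translation invariance of the variance
  shifted <- dfc
  shifted$r <- dfc$r + 0.3
  ess <- temporal_edge_stats(shifted)
  expect_equal(ess$strength[1, 2], 0.7, tolerance = 1e-12)
  expect_equal(ess$variability[1, 2], es$variability[1, 2],
               tolerance = 1e-12)
})

test_that("edge statistics agree with a two-pass oracle on random series", {
  set.seed(4)
  x <- matrix(rnorm(60 * 6), 60, 6)
  dfc <- sliding_window_dfc(x, window_spec(20, 5))
  es <- temporal_edge_stats(dfc)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      series <- dfc$r[i, j, ]
      m <- sum(series) / length(series)
      v <- sum((series - m)^2) / (length(series) - 1)
      expect_equal(es$strength[i, j], m, tolerance = 1e-12)
      expect_equal(es$variability[i, j], v, tolerance = 1e-12)
    }
  }
})

test_that("affine rescaling of regions leaves the correlations unchanged", {
  set.seed(5)
  x <- matrix(rnorm(50 * 4), 50, 4)
  scale <- c(2.5, 0.3, 10, 1)
  shift <- c(-3, 7, 0, 100)
  y <- sweep(sweep(x, 2, scale, `*`), 2, shift, `+`)
  a <- sliding_window_dfc(x, window_spec(10, 7))
  b <- sliding_window_dfc(y, window_spec(10, 7))
  expect_equal(a$r, b$r, tolerance = 1e-12)
})

test_that("edge categories partition all pairs", {
  parc <- generate_parcellation(45, seed = 6)
  cats <- classify_edges(parc)
  tab <- table(cats)
  expect_equal(unname(tab["homotopic"]), 45, ignore_attr = TRUE)
  expect_equal(unname(tab["heterotopic"]), 1980, ignore_attr = TRUE)
  expect_equal(unname(tab["intrahemispheric"]), 1980, ignore_attr = TRUE)
  expect_equal(sum(tab), 90 * 89 / 2)

  small <- generate_parcellation(2, seed = 6)
  stab <- table(classify_edges(small))
  expect_equal(as.integer(stab), c(2L, 2L, 2L))
})

test_that("category permutation test is label-driven and seed-stable", {
  parc <- generate_parcellation(6, seed = 7)
  cats <- classify_edges(parc)
  set.seed(8)
  vals <- rnorm(length(cats))
  res <- category_comparison(vals, cats, n_perm = 500, seed = 1)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_value))
  # observed statistic depends only on labels, not edge order within label
  hom <- which(cats == "homotopic")
  het <- which(cats == "heterotopic")
  obs <- mean(vals[hom]) - mean(vals[het])
  hh <- res[res$category_a == "homotopic" &
              res$category_b == "heterotopic", ]
  expect_equal(hh$observed_diff, obs, tolerance = 1e-12)
  # two seeds agree within permutation noise
  res2 <- category_comparison(vals, cats, n_perm = 2000, seed = 10)
  res3 <- category_comparison(vals, cats, n_perm = 2000, seed = 20)
  p2 <- res2$p_value
  p3 <- res3$p_value
  # both p's are Monte-Carlo estimates, so the difference has variance
  # 2 p(1-p)/n_perm
  expect_true(all(abs(p2 - p3) < 3 * sqrt(2 * p2 * (1 - p2) / 2000) + 2e-3))
})
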