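#' Per-window network topology of a dynamic connectivity series
#'
#' Thresholds every window's correlation matrix under one policy and
#' computes the global metrics (and, optionally, their random-network
#' normalized versions with `n_rand` degree-preserving nulls per window)
#' plus the nodal degree vector. Per-window null ensembles derive their
#' seeds from one base seed plus the window index, so runs are reproducible
#' without inter-window correlation.
#'
#' @param dfc A `dfc_series`.
#' @param policy A [threshold_policy()].
#' @param n_rand Nulls per window for gamma/lambda/sigma/alpha_z; 0 skips
#'   normalization.
#' @param swaps_per_edge Attempted swaps per edge per null.
#' @param seed Integer base seed.
#' @return A `metric_series` list: `global` (data frame, one row per
#'   window: S, Cp, Lp, gamma, lambda, sigma, alpha, alpha_z, component
#'   census), `degree` (T_w x N matrix), `onsets`.
#' @export
metric_time_series <- function(dfc, policy = threshold_policy(),
                               n_rand = 100L, swaps_per_edge = 10L,
                               seed = 1L) {
  tw <- dfc$n_windows
  n <- dim(dfc$r)[1L]
  n_samples <- dfc$spec$length
  deg <- matrix(NA_integer_, tw, n)
  rows <- vector("list", tw)
  for (t in seq_len(tw)) {
    res <- tryCatch({
      g <- binarize(dfc$r[, , t], policy, n_samples = n_samples)
      gm <- global_metrics(g)
      nm <- if (n_rand > 0L) {
        normalized_metrics(g, n_rand = n_rand,
                           swaps_per_edge = swaps_per_edge,
                           seed = derive_seed(seed, t))
      } else {
        list(gamma = NA_real_, lambda = NA_real_, sigma = NA_real_,
             alpha_z = NA_real_)
      }
      deg[t, ] <- degree_centrality(g)
      data.frame(window = t, sparsity = gm$sparsity, cp = gm$cp, lp = gm$lp,
                 gamma = nm$gamma, lambda = nm$lambda, sigma = nm$sigma,
                 alpha = gm$assortativity, alpha_z = nm$alpha_z,
                 n_components = gm$n_components,
                 largest_component = gm$largest_component)
    }, error = function(e) {
      stop("window ", t, ": ", conditionMessage(e), call. = FALSE)
    })
    rows[[t]] <- res
  }
  structure(list(global = do.call(rbind, rows), degree = deg,
                 onsets = dfc$onsets),
            class = "metric_series")
}

#' Temporal mean and variability of every global metric
#'
#' Applies the same mean / unbiased-variance kernel used for edge
#' statistics to each global metric's across-window series.
#'
#' @param series A `metric_series` (or a data frame of per-window metrics).
#' @param variability `"var"` (default) or `"std"`.
#' @return Data frame with one row per metric: `tmean`, `tvar`.
#' @export
temporal_metric_stats <- function(series, variability = c("var", "std")) {
  variability <- match.arg(variability)
  g <- if (inherits(series, "metric_series")) series$global else series
  metrics <- setdiff(names(g), c("window", "n_components",
                                 "largest_component"))
  out <- lapply(metrics, function(mname) {
    x <- g[[mname]]
    x <- x[is.finite(x)]
    if (length(x) < 2L) {
      return(data.frame(metric = mname, tmean = NA_real_, tvar = NA_real_))
    }
    st <- temporal_stats(x, variability)
    data.frame(metric = mname, tmean = st$mean, tvar = st$variability,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalized histogram and group averaging
#'
#' Histogram whose bin masses sum to one. Bin edges are shared across
#' participants (an explicit `breaks` vector) so group averaging is
#' well defined; the group average preserves normalization and carries the
#' per-bin standard deviation across participants.
#'
#' @param values Numeric vector (at least one value).
#' @param breaks Either a single bin count or an explicit vector of edges
#'   covering the data range.
#' @return List with `breaks`, `mids`, `mass` (sums to 1).
#' @export
normalized_histogram <- function(values, breaks = 20L) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("histogram undefined for empty input",
                            call. = FALSE)
  if (length(breaks) == 1L) {
    rng <- range(values)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = breaks + 1L)
  }
  h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  list(breaks = h$breaks, mids = h$mids, mass = h$counts / sum(h$counts))
}

#' @rdname normalized_histogram
#' @param histograms List of [normalized_histogram()] results on identical
#'   breaks.
#' @return For `average_histograms`: list with `breaks`, `mids`,
#'   `mass` (mean across participants, still summing to 1) and `sd`.
#' @export
average_histograms <- function(histograms) {
  stopifnot(length(histograms) >= 1L)
  br <- histograms[[1L]]$breaks
  for (h in histograms) {
    if (!isTRUE(all.equal(h$breaks, br))) {
      stop("histograms must share identical bin edges", call. = FALSE)
    }
  }
  m <- do.call(rbind, lapply(histograms, `[[`, "mass"))
  list(breaks = br, mids = histograms[[1L]]$mids,
       mass = colMeans(m), sd = apply(m, 2L, sd))
}

#' Hubs of a single window
#'
#' A node is a hub when its degree strictly exceeds the mean degree across
#' the brain; in a regular graph no node qualifies.
#'
#' @param degree Integer degree vector.
#' @return Logical vector.
#' @export
window_hubs <- function(degree) {
  if (length(degree) < 2L) stop("need at least 2 nodes", call. = FALSE)
  degree > mean(degree)
}

#' Hub persistence across windows
#'
#' Per node: the occurrence probability as a hub (fraction of windows in
#' which its degree exceeds the mean), a persistence flag at strictly
#' greater than 0.5, and the temporal variability of its degree (same
#' unbiased-variance kernel as the edge statistics).
#'
#' @param degree T_w x N degree matrix (rows = windows), or a
#'   `metric_series`.
#' @param cutoff Persistence cutoff on the probability (strict; default
#'   0.5).
#' @param variability `"var"` (default) or `"std"`.
#' @return A `hub_profile` data frame: `node`, `probability`, `persistent`,
#'   `degree_tvar`.
#' @export
hub_persistence <- function(degree, cutoff = 0.5,
                            variability = c("var", "std")) {
  variability <- match.arg(variability)
  if (inherits(degree, "metric_series")) degree <- degree$degree
  stopifnot(is.matrix(degree), nrow(degree) >= 1L)
  hubs <- t(apply(degree, 1L, window_hubs))
  if (nrow(degree) == 1L) hubs <- matrix(hubs, nrow = 1L)
  prob <- colMeans(hubs)
  tvar <- if (nrow(degree) >= 2L) {
    apply(degree, 2L, function(x) temporal_stats(x, variability)$variability)
  } else {
    rep(NA_real_, ncol(degree))
  }
  structure(
    data.frame(node = seq_len(ncol(degree)) - 1L, probability = prob,
               persistent = prob > cutoff, degree_tvar = tvar),
    class = c("hub_profile", "data.frame")
  )
}
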