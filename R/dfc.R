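#' Sliding-window specification
#'
#' Windows are left-aligned: onsets 0, step, 2*step, ... (0-based samples).
#' A window length in seconds is converted to samples with
#' `round(seconds / TR)`; 100 s at TR = 0.645 s gives 155 samples.
#'
#' @param length Window length in samples (> 2).
#' @param step Step between consecutive window onsets in samples (>= 1).
#' @return A `window_spec` list.
#' @export
window_spec <- function(length, step = 1L) {
  if (length <= 2) stop("window `length` must exceed 2 samples", call. = FALSE)
  if (step < 1) stop("`step` must be >= 1", call. = FALSE)
  structure(list(length = as.integer(length), step = as.integer(step)),
            class = "window_spec")
}

#' @rdname window_spec
#' @param seconds Window length in seconds.
#' @param sampling_interval Sampling interval (TR) in seconds.
#' @export
window_spec_seconds <- function(seconds, sampling_interval, step = 1L) {
  window_spec(round(seconds / sampling_interval), step)
}

#' Number of sliding windows
#'
#' `floor((T - L) / step) + 1` for series length T, window length L.
#'
#' @param n_timepoints Series length T.
#' @param spec A [window_spec()].
#' @return Integer window count.
#' @export
window_count <- function(n_timepoints, spec) {
  if (spec$length > n_timepoints) {
    stop("invalid window: length ", spec$length, " exceeds series length ",
         n_timepoints, call. = FALSE)
  }
  as.integer(floor((n_timepoints - spec$length) / spec$step) + 1L)
}

as_ts_matrix <- function(ts) {
  if (inherits(ts, "regional_ts")) ts$values else as.matrix(ts)
}

#' Sliding-window dynamic functional connectivity
#'
#' For each window, the Pearson correlation matrix of the `L` samples
#' starting at that onset, for every region pair. Fails fast if any region
#' is constant within a window (the correlation would be undefined).
#'
#' @param ts A `regional_ts` or a T x N numeric matrix.
#' @param spec A [window_spec()].
#' @return A `dfc_series`: list with `r` (N x N x T_w array of correlation
#'   matrices, unit diagonal by convention, never consumed), `onsets`
#'   (0-based sample indices) and `spec`.
#' @export
sliding_window_dfc <- function(ts, spec) {
  x <- as_ts_matrix(ts)
  tw <- window_count(nrow(x), spec)
  n <- ncol(x)
  onsets <- (seq_len(tw) - 1L) * spec$step
  r <- array(NA_real_, dim = c(n, n, tw))
  for (t in seq_len(tw)) {
    seg <- x[(onsets[t] + 1L):(onsets[t] + spec$length), , drop = FALSE]
    sds <- apply(seg, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("undefined correlation: region ", which(sds == 0)[1L],
           " is constant within window ", t, call. = FALSE)
    }
    r[, , t] <- cor(seg)
  }
  structure(list(r = r, onsets = onsets, spec = spec, n_windows = tw),
            class = "dfc_series")
}

#' Static functional connectivity
#'
#' Pearson correlation over the whole-scan time courses.
#'
#' @param ts A `regional_ts` or T x N matrix with T >= 3.
#' @return Symmetric N x N correlation matrix.
#' @export
static_fc <- function(ts) {
  x <- as_ts_matrix(ts)
  if (nrow(x) < 3L) stop("need at least 3 time points", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("undefined correlation: region ", which(sds == 0)[1L],
         " is constant", call. = FALSE)
  }
  cor(x)
}

#' Fisher r-to-z transformation
#'
#' Elementwise `atanh(r)`. With `clip = TRUE` (the default), correlations
#' are first clipped to +/- (1 - 1e-12) so that exact unit correlations map
#' to a large finite z rather than infinity.
#'
#' @param r Numeric vector, matrix or array of Pearson correlations.
#' @param clip Clip |r| to 1 - 1e-12 before transforming.
#' @return Object of the same shape.
#' @export
fisher_z <- function(r, clip = TRUE) {
  if (clip) {
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  } else if (any(abs(r) >= 1)) {
    stop("|r| = 1 is outside the domain of atanh with clipping disabled",
         call. = FALSE)
  }
  atanh(r)
}

#' Spatial similarity between static and dynamic connectivity
#'
#' For each window, the Pearson correlation between the Fisher-z upper
#' triangles (diagonal excluded) of the static matrix and of that window's
#' dynamic matrix.
#'
#' @param sfc Static correlation matrix.
#' @param dfc A `dfc_series` on the same regions.
#' @return Numeric vector of length `n_windows`.
#' @export
spatial_similarity <- function(sfc, dfc) {
  n <- nrow(sfc)
  if (n < 3L) stop("too few edges: need at least 3 regions", call. = FALSE)
  stopifnot(dim(dfc$r)[1L] == n)
  zs <- fisher_z(upper_values(sfc))
  vapply(seq_len(dfc$n_windows), function(t) {
    cor(zs, fisher_z(upper_values(dfc$r[, , t])))
  }, numeric(1))
}

#' Temporal strength and variability of every edge
#'
#' Edge strength is the arithmetic mean of the raw windowed correlations
#' (negatives included); variability is the unbiased sample variance across
#' windows (or its square root with `variability = "std"`).
#'
#' @param dfc A `dfc_series` with at least 2 windows.
#' @param variability `"var"` (default) or `"std"`.
#' @return An `edge_stats` list with symmetric N x N matrices `strength` and
#'   `variability` (zero diagonal).
#' @export
temporal_edge_stats <- function(dfc, variability = c("var", "std")) {
  variability <- match.arg(variability)
  tw <- dfc$n_windows
  if (tw < 2L) {
    stop("temporal variability undefined for fewer than 2 windows",
         call. = FALSE)
  }
  n <- dim(dfc$r)[1L]
  flat <- matrix(dfc$r, n * n, tw) # one row per (i, j) cell
  m <- rowMeans(flat)
  v <- rowSums((flat - m)^2) / (tw - 1L)
  if (variability == "std") v <- sqrt(v)
  strength <- matrix(m, n, n)
  variab <- matrix(v, n, n)
  diag(strength) <- 0
  diag(variab) <- 0
  structure(list(strength = strength, variability = variab,
                 n_windows = tw, variability_kind = variability),
            class = "edge_stats")
}

#' Classify region pairs as homotopic, heterotopic or intrahemispheric
#'
#' Homotopic pairs connect a region with its contralateral homolog;
#' heterotopic pairs are the remaining interhemispheric pairs;
#' intrahemispheric pairs share a hemisphere. The three categories
#' partition all N(N-1)/2 unordered pairs.
#'
#' @param parcellation A parcellation table.
#' @return An `edge_categories` object: factor vector in canonical edge
#'   order with attribute `index` (the [edge_index()] table).
#' @export
classify_edges <- function(parcellation) {
  validate_parcellation(parcellation)
  n <- nrow(parcellation)
  ord <- match(0:(n - 1L), parcellation$region_id)
  hemi <- parcellation$hemisphere[ord]
  hm <- parcellation$homolog_id[ord] + 1L
  ei <- edge_index(n)
  same_hemi <- hemi[ei[, 1]] == hemi[ei[, 2]]
  homot <- hm[ei[, 1]] == ei[, 2]
  cat <- ifelse(same_hemi, "intrahemispheric",
                ifelse(homot, "homotopic", "heterotopic"))
  structure(factor(cat, levels = c("homotopic", "heterotopic",
                                   "intrahemispheric")),
            index = ei, class = c("edge_categories", "factor"))
}

# Two-sided label-permutation test for a difference of group means with the
# add-one p estimator. Shared by the category and SC-presence tests.
permute_mean_diff <- function(x, group, n_perm, seed) {
  stopifnot(is.logical(group), length(x) == length(group))
  n1 <- sum(group)
  n2 <- sum(!group)
  if (n1 < 2L || n2 < 2L) {
    stop("degenerate groups: each group needs at least 2 values",
         call. = FALSE)
  }
  obs <- mean(x[group]) - mean(x[!group])
  total <- sum(x)
  ntot <- length(x)
  with_local_seed(seed, {
    null <- vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(ntot, n1)
      s1 <- sum(x[idx])
      s1 / n1 - (total - s1) / n2
    }, numeric(1))
    p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
    structure(
      list(observed = obs, null_mean = mean(null), null_sd = sd(null),
           p_value = p, n_perm = n_perm, direction = "two_sided",
           n_group1 = n1, n_group2 = n2),
      class = "permutation_result"
    )
  })
}

#' Permutation comparison of edge statistics across spatial categories
#'
#' For each of the three category pairs (homotopic vs heterotopic,
#' homotopic vs intrahemispheric, heterotopic vs intrahemispheric), the
#' observed statistic is the difference of category means; category labels
#' are shuffled to build the null, and p-values are Bonferroni-adjusted by
#' the fixed factor 3.
#'
#' @param values Symmetric N x N edge-statistic matrix (e.g. strength or
#'   variability), or a vector already in canonical edge order.
#' @param categories An [classify_edges()] result.
#' @param n_perm Number of label shuffles (>= 100).
#' @param seed Integer seed.
#' @return Data frame with one row per category pair: observed difference,
#'   raw and Bonferroni-adjusted p-values.
#' @export
category_comparison <- function(values, categories, n_perm = 10000L,
                                seed = 1L) {
  if (n_perm < 100L) stop("`n_perm` must be >= 100", call. = FALSE)
  v <- if (is.matrix(values)) upper_values(values) else as.numeric(values)
  stopifnot(length(v) == length(categories))
  pairs <- utils::combn(levels(categories), 2L)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]
    b <- pairs[2L, k]
    keep <- categories %in% c(a, b)
    res <- permute_mean_diff(v[keep], categories[keep] == a,
                             n_perm, derive_seed(seed, k))
    data.frame(category_a = a, category_b = b,
               observed_diff = res$observed, p_value = res$p_value,
               p_adjusted = min(1, 3 * res$p_value),
               n_a = res$n_group1, n_b = res$n_group2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
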