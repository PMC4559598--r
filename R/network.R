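#' Correlation threshold from a Bonferroni-corrected significance level
#'
#' Maps a corrected significance level to a positive correlation cutoff:
#' the per-edge level is `alpha_corr / (N(N-1)/2)`, and tau is the positive
#' r whose two-sided Pearson test at `df = n_samples - 2` attains exactly
#' that level, via `r = t / sqrt(df + t^2)`. A one-sided variant is
#' available; negatives are excluded downstream either way.
#'
#' @param n_samples Number of samples the correlations were computed from
#'   (window length; >= 4).
#' @param n_regions Number of regions N.
#' @param alpha_corr Corrected significance level in (0, 1).
#' @param sided `"two"` (default) or `"one"`.
#' @return Positive correlation threshold tau.
#' @export
bonferroni_r_threshold <- function(n_samples, n_regions, alpha_corr = 0.01,
                                   sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (n_samples < 4L) stop("`n_samples` must be >= 4", call. = FALSE)
  if (alpha_corr <= 0 || alpha_corr > 1) {
    stop("`alpha_corr` must be in (0, 1]", call. = FALSE)
  }
  n_edges <- n_regions * (n_regions - 1) / 2
  alpha_edge <- alpha_corr / n_edges
  if (alpha_edge < .Machine$double.xmin * 10) {
    stop("per-edge alpha underflows", call. = FALSE)
  }
  df <- n_samples - 2
  tail <- if (sided == "two") alpha_edge / 2 else alpha_edge
  tcrit <- qt(tail, df = df, lower.tail = FALSE)
  tcrit / sqrt(df + tcrit^2)
}

#' Thresholding policy for network construction
#'
#' Exactly one mode is active: `bonferroni_r` (significance-based cutoff,
#' the default analysis), `fixed_r` (explicit tau) or `sparsity` (top
#' positive correlations at a target density).
#'
#' @param mode One of `"bonferroni_r"`, `"fixed_r"`, `"sparsity"`.
#' @param alpha_corr Corrected alpha for `bonferroni_r`.
#' @param tau Correlation cutoff for `fixed_r`.
#' @param target_sparsity Density in (0, 1) for `sparsity`.
#' @param sided Sidedness of the Bonferroni per-edge test.
#' @return A `threshold_policy` list.
#' @export
threshold_policy <- function(mode = c("bonferroni_r", "fixed_r", "sparsity"),
                             alpha_corr = 0.01, tau = NULL,
                             target_sparsity = NULL, sided = "two") {
  mode <- match.arg(mode)
  if (mode == "fixed_r" && is.null(tau)) {
    stop("fixed_r mode requires `tau`", call. = FALSE)
  }
  if (mode == "sparsity" &&
      (is.null(target_sparsity) || target_sparsity <= 0 ||
       target_sparsity >= 1)) {
    stop("sparsity mode requires `target_sparsity` in (0, 1)", call. = FALSE)
  }
  structure(list(mode = mode, alpha_corr = alpha_corr, tau = tau,
                 target_sparsity = target_sparsity, sided = sided),
            class = "threshold_policy")
}

resolve_tau <- function(policy, n_samples, n_regions) {
  switch(policy$mode,
    bonferroni_r = {
      if (is.null(n_samples)) {
        stop("bonferroni_r mode needs `n_samples` (the window length)",
             call. = FALSE)
      }
      bonferroni_r_threshold(n_samples, n_regions, policy$alpha_corr,
                             policy$sided)
    },
    fixed_r = policy$tau,
    sparsity = NULL
  )
}

# Edge selection common to binarize()/weight_graph(): returns a logical
# vector over canonical edge order.
select_edges <- function(r_values, ei, policy, tau) {
  if (policy$mode == "sparsity") {
    n_edges <- length(r_values)
    k <- floor(policy$target_sparsity * n_edges)
    pos <- which(r_values > 0)
    if (length(pos) < k) {
      warning("only ", length(pos), " positive correlations available for ",
              k, " requested edges; achieved sparsity ",
              format(length(pos) / n_edges, digits = 3), call. = FALSE)
      k <- length(pos)
    }
    # ties: descending r, then ascending (i, j) lexicographic
    ord <- pos[order(-r_values[pos], ei[pos, 1L], ei[pos, 2L])]
    sel <- logical(n_edges)
    sel[head(ord, k)] <- TRUE
    sel
  } else {
    r_values > tau & r_values > 0
  }
}

#' Binary graph from a correlation matrix
#'
#' Retains edges with correlation strictly greater than the policy's
#' threshold; negative correlations are always excluded. In sparsity mode
#' the top `floor(S * N(N-1)/2)` positive correlations are kept, with ties
#' broken by descending r then ascending (i, j).
#'
#' @param m Symmetric correlation matrix.
#' @param policy A [threshold_policy()].
#' @param n_samples Window length, needed to resolve a Bonferroni cutoff.
#' @return A `binary_graph`: list with `adjacency` (0/1 matrix, zero
#'   diagonal), `n_nodes`, `n_edges`, `tau` (NA in sparsity mode).
#' @export
binarize <- function(m, policy = threshold_policy(), n_samples = NULL) {
  check_square_symmetric(m, tol = 1e-8, what = "correlation matrix")
  n <- nrow(m)
  ei <- edge_index(n)
  tau <- resolve_tau(policy, n_samples, n)
  sel <- select_edges(m[ei], ei, policy, tau)
  adj <- matrix_from_upper(as.numeric(sel), n)
  structure(list(adjacency = adj, n_nodes = n, n_edges = sum(sel),
                 tau = if (is.null(tau)) NA_real_ else tau),
            class = "binary_graph")
}

#' Weighted graph from a correlation matrix
#'
#' Same edge set as [binarize()] under the same policy, but the retained
#' correlation values are kept as weights.
#'
#' @inheritParams binarize
#' @return A `weighted_graph`: list with `weights` (symmetric nonnegative
#'   matrix, zero diagonal), `n_nodes`, `n_edges`.
#' @export
weight_graph <- function(m, policy = threshold_policy(), n_samples = NULL) {
  check_square_symmetric(m, tol = 1e-8, what = "correlation matrix")
  n <- nrow(m)
  ei <- edge_index(n)
  tau <- resolve_tau(policy, n_samples, n)
  rv <- m[ei]
  sel <- select_edges(rv, ei, policy, tau)
  w <- matrix_from_upper(ifelse(sel, rv, 0), n)
  structure(list(weights = w, n_nodes = n, n_edges = sum(sel)),
            class = "weighted_graph")
}
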