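#' Rank-based inverse-normal ("Gaussian resampling") transform
#'
#' Maps values through their average ranks to rankit plotting positions
#' `(rank - 0.5) / n`, through the standard normal quantile, and onto a
#' target mean and standard deviation (default 0.5 +/- 0.1). Strictly rank
#' preserving for untied values; ties share a value. Used to normalize
#' connection-strength distributions before Pearson correlation.
#'
#' @param values Numeric vector (n >= 2, not all identical).
#' @param target_mean,target_sd Moments of the transformed scale.
#' @return Numeric vector of the same length.
#' @export
gaussian_resample <- function(values, target_mean = 0.5, target_sd = 0.1) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values", call. = FALSE)
  if (length(unique(values)) == 1L) {
    stop("degenerate input: all values identical", call. = FALSE)
  }
  r <- rank(values, ties.method = "average")
  qnorm((r - 0.5) / n) * target_sd + target_mean
}

mask_upper <- function(sc) {
  w <- if (inherits(sc, c("structural_network", "backbone_network"))) {
    sc$weights
  } else {
    sc
  }
  list(present = upper_values(w) > 0, weights = upper_values(w))
}

#' Permutation test of edge statistics by structural-connection presence
#'
#' Tests whether D-FC strength and variability differ between region pairs
#' with a direct structural connection and those without: the observed
#' statistic is mean(SC present) - mean(SC absent), edge labels are
#' shuffled `n_perm` times, and the two-sided p uses the add-one
#' estimator.
#'
#' @param edge_stats An [temporal_edge_stats()] result.
#' @param sc A `structural_network`, `backbone_network` or weight matrix.
#' @param n_perm Number of shuffles.
#' @param seed Integer seed.
#' @return Data frame with one row per statistic (`strength`,
#'   `variability`): observed difference, p-value, group sizes.
#' @export
sc_presence_test <- function(edge_stats, sc, n_perm = 10000L, seed = 1L) {
  msk <- mask_upper(sc)
  present <- msk$present
  if (!any(present) || all(present)) {
    stop("degenerate groups: need both SC-present and SC-absent edges",
         call. = FALSE)
  }
  out <- lapply(c("strength", "variability"), function(stat) {
    v <- upper_values(edge_stats[[stat]])
    res <- permute_mean_diff(v, present, n_perm,
                             derive_seed(seed, match(stat, c("strength",
                                                             "variability"))))
    data.frame(statistic = stat, observed_diff = res$observed,
               null_mean = res$null_mean, null_sd = res$null_sd,
               p_value = res$p_value, n_present = res$n_group1,
               n_absent = res$n_group2, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation between structural strength and D-FC temporal statistics
#'
#' Restricted to region pairs with a direct structural connection: Pearson
#' correlation (with the t-approximation p-value at df = n - 2) between SC
#' strength and D-FC strength, and between SC strength and D-FC
#' variability. With `resample = TRUE` (default) every variable is first
#' passed through [gaussian_resample()].
#'
#' @param edge_stats An [temporal_edge_stats()] result.
#' @param sc A `structural_network`, `backbone_network` or weight matrix.
#' @param resample Apply the rank-based inverse-normal transform first.
#' @return A `coupling_report` list: `r_strength_sc`, `p_strength_sc`,
#'   `r_variability_sc`, `p_variability_sc`, `n_edges_sc_present`,
#'   `resampled`.
#' @export
sc_strength_coupling <- function(edge_stats, sc, resample = TRUE) {
  msk <- mask_upper(sc)
  keep <- msk$present
  if (sum(keep) < 3L) {
    stop("insufficient data: need >= 3 SC-present edges", call. = FALSE)
  }
  scv <- msk$weights[keep]
  st <- upper_values(edge_stats$strength)[keep]
  vr <- upper_values(edge_stats$variability)[keep]
  if (resample) {
    scv <- gaussian_resample(scv)
    st <- gaussian_resample(st)
    vr <- gaussian_resample(vr)
  }
  cs <- cor.test(scv, st)
  cv <- cor.test(scv, vr)
  structure(
    list(r_strength_sc = unname(cs$estimate),
         p_strength_sc = cs$p.value,
         r_variability_sc = unname(cv$estimate),
         p_variability_sc = cv$p.value,
         n_edges_sc_present = sum(keep), resampled = resample),
    class = "coupling_report"
  )
}

#' Across-subject coupling of global topology
#'
#' For each global metric, Pearson correlation across subjects between the
#' structural-network value and a temporal feature (tMean or tVar) of the
#' dynamic functional networks.
#'
#' @param sc_metrics Data frame, one row per subject, columns = structural
#'   global metrics.
#' @param dfc_features Data frame, same subjects/rows, columns = the
#'   temporal feature of the matching functional metrics.
#' @return Data frame with one row per shared metric: `r`, `p`, `n`.
#' @export
global_topology_coupling <- function(sc_metrics, dfc_features) {
  if (nrow(sc_metrics) < 3L) {
    stop("insufficient data: need >= 3 subjects", call. = FALSE)
  }
  stopifnot(nrow(sc_metrics) == nrow(dfc_features))
  shared <- intersect(names(sc_metrics), names(dfc_features))
  if (!length(shared)) stop("no shared metric columns", call. = FALSE)
  out <- lapply(shared, function(mname) {
    x <- sc_metrics[[mname]]
    y <- dfc_features[[mname]]
    ok <- is.finite(x) & is.finite(y)
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      stop("correlation undefined: metric ", mname,
           " is constant across subjects", call. = FALSE)
    }
    ct <- cor.test(x[ok], y[ok])
    data.frame(metric = mname, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman correlation for nodal structure-function coupling
#'
#' Rank correlation (average ranks for ties, t-approximation p-value)
#' between the temporal variability of functional degree centrality and a
#' structural nodal property — hub occurrence probability (discrete, hence
#' Spearman) or degree centrality.
#'
#' @param functional_degree_tvar Per-node temporal variability of
#'   functional degree.
#' @param structural_values Per-node structural property (hub probability
#'   or degree).
#' @return List with `rho`, `p`, `n`.
#' @export
nodal_coupling <- function(functional_degree_tvar, structural_values) {
  stopifnot(length(functional_degree_tvar) == length(structural_values))
  n <- length(structural_values)
  if (n < 5L) stop("need at least 5 nodes", call. = FALSE)
  if (sd(functional_degree_tvar) == 0 || sd(structural_values) == 0) {
    stop("correlation undefined: constant input", call. = FALSE)
  }
  ct <- suppressWarnings(
    cor.test(functional_degree_tvar, structural_values,
             method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}
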