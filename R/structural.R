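#' Structural network from streamline counts
#'
#' Connection strength is the normalized streamline number: the count of
#' interconnecting streamlines divided by the mean volume of the two
#' regions.
#'
#' @param counts Symmetric nonnegative integer matrix, zero diagonal.
#' @param parcellation The matching parcellation (supplies volumes).
#' @param subject_id Label.
#' @return A `structural_network`: list with `weights` (symmetric,
#'   nonnegative, zero diagonal) and `subject_id`.
#' @export
sc_from_streamlines <- function(counts, parcellation,
                                subject_id = "subject") {
  validate_parcellation(parcellation)
  check_square_symmetric(counts, what = "streamline count matrix")
  if (any(counts < 0)) stop("streamline counts must be nonnegative",
                            call. = FALSE)
  if (any(diag(counts) != 0)) stop("count diagonal must be zero",
                                   call. = FALSE)
  n <- nrow(parcellation)
  stopifnot(nrow(counts) == n)
  vol <- parcellation$volume[match(0:(n - 1L), parcellation$region_id)]
  vmean <- outer(vol, vol, function(a, b) (a + b) / 2)
  w <- counts / vmean
  diag(w) <- 0
  structure(list(weights = w, subject_id = subject_id),
            class = "structural_network")
}

#' One-tailed sign-test p-value for edge presence
#'
#' Exact binomial upper tail `P(X >= k | n, 1/2)` for `k` subjects showing
#' the connection out of `n`: the null hypothesis is that no connection
#' exists, so presence and absence are equally likely. Zeros count as
#' failures, which keeps the test exact.
#'
#' @param k Number of subjects with a strictly positive weight.
#' @param n Number of subjects.
#' @return p-value.
#' @export
sign_test_presence <- function(k, n) {
  stopifnot(k >= 0, k <= n, n >= 1)
  pbinom(k - 1, size = n, prob = 0.5, lower.tail = FALSE)
}

#' Group structural backbone
#'
#' Retains edges whose across-subject presence rejects the one-tailed sign
#' test at `alpha`; retained edges carry the mean normalized streamline
#' number across all subjects (zeros included). Everything else is zero.
#'
#' @param networks List of `structural_network` objects on one
#'   parcellation (>= 2 subjects).
#' @param alpha Significance level (default 0.05).
#' @param mean_over One of `"all"` (default: average over every subject)
#'   or `"nonzero"` (average over subjects that have the edge).
#' @return A `backbone_network`: list with `weights`, `p_values`
#'   (symmetric matrix of sign-test p-values), `n_subjects`, `alpha`.
#' @export
group_backbone <- function(networks, alpha = 0.05,
                           mean_over = c("all", "nonzero")) {
  mean_over <- match.arg(mean_over)
  stopifnot(length(networks) >= 2L)
  n <- nrow(networks[[1L]]$weights)
  for (nw in networks) {
    if (nrow(nw$weights) != n) {
      stop("inconsistent region count across subjects", call. = FALSE)
    }
  }
  ns <- length(networks)
  stack <- vapply(networks, function(nw) upper_values(nw$weights),
                  numeric(n * (n - 1) / 2))
  present <- stack > 0
  k <- rowSums(present)
  p <- sign_test_presence(k, ns)
  keep <- p < alpha
  wbar <- if (mean_over == "all") {
    rowMeans(stack)
  } else {
    ifelse(k > 0, rowSums(stack) / pmax(k, 1L), 0)
  }
  structure(
    list(weights = matrix_from_upper(ifelse(keep, wbar, 0), n),
         p_values = matrix_from_upper(p, n),
         n_subjects = ns, alpha = alpha),
    class = "backbone_network"
  )
}

#' Structural hub profile across subjects
#'
#' Per subject, the structural network is binarized at weight > 0, nodal
#' degree is computed, and hubs are nodes whose degree strictly exceeds
#' the mean. The profile reports the across-subject hub occurrence
#' probability, the persistence flag (probability strictly above 0.5) and
#' the mean structural degree.
#'
#' @param networks List of `structural_network` objects (>= 1).
#' @return A `hub_profile` data frame: `node`, `probability`,
#'   `persistent`, `mean_degree`.
#' @export
structural_hub_profile <- function(networks) {
  stopifnot(length(networks) >= 1L)
  degs <- vapply(networks, function(nw) {
    as.numeric(degree_centrality((nw$weights > 0) * 1))
  }, numeric(nrow(networks[[1L]]$weights)))
  degs <- t(degs) # subjects x nodes
  hubs <- t(apply(degs, 1L, window_hubs))
  if (nrow(degs) == 1L) hubs <- matrix(hubs, nrow = 1L)
  prob <- colMeans(hubs)
  structure(
    data.frame(node = seq_len(ncol(degs)) - 1L, probability = prob,
               persistent = prob > 0.5, mean_degree = colMeans(degs)),
    class = c("hub_profile", "data.frame")
  )
}
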