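#' Generate a synthetic parcellation of homologous region pairs
#'
#' Builds a parcellation table of `2 * n_pairs` regions in which every left
#' hemisphere region has exactly one right-hemisphere homolog. Region ids are
#' 0-based and contiguous; regions `0 .. n_pairs-1` form the left hemisphere
#' and `n_pairs .. 2*n_pairs-1` the right, with `homolog(i) = i + n_pairs`
#' (mod `2 * n_pairs`). Region volumes are drawn log-normally per homologous
#' pair with a small independent per-region jitter, so homologs have similar
#' but not identical volumes.
#'
#' @param n_pairs Number of homologous pairs (>= 2).
#' @param seed Integer seed; identical calls are bit-identical.
#' @param volume_meanlog,volume_sdlog Log-normal parameters of the per-pair
#'   base volume (arbitrary volume units).
#' @return A `parcellation` data frame with columns `region_id`, `name`,
#'   `hemisphere`, `homolog_id`, `volume`.
#' @export
generate_parcellation <- function(n_pairs, seed,
                                  volume_meanlog = log(8),
                                  volume_sdlog = 0.3) {
  if (!is.numeric(n_pairs) || n_pairs < 2) {
    stop("`n_pairs` must be an integer >= 2", call. = FALSE)
  }
  n_pairs <- as.integer(n_pairs)
  n <- 2L * n_pairs
  with_local_seed(seed, {
    base <- rlnorm(n_pairs, meanlog = volume_meanlog, sdlog = volume_sdlog)
    jitter <- rlnorm(n, meanlog = 0, sdlog = 0.1)
    vol <- rep(base, 2L) * jitter
    out <- data.frame(
      region_id = 0:(n - 1L),
      name = c(sprintf("L%02d", seq_len(n_pairs)),
               sprintf("R%02d", seq_len(n_pairs))),
      hemisphere = rep(c("L", "R"), each = n_pairs),
      homolog_id = c(n_pairs:(n - 1L), 0:(n_pairs - 1L)),
      volume = vol,
      stringsAsFactors = FALSE
    )
    class(out) <- c("parcellation", "data.frame")
    out
  })
}

validate_parcellation <- function(parc) {
  need <- c("region_id", "hemisphere", "homolog_id", "volume")
  if (!all(need %in% names(parc))) {
    stop("parcellation is missing columns: ",
         paste(setdiff(need, names(parc)), collapse = ", "), call. = FALSE)
  }
  n <- nrow(parc)
  if (!identical(sort(parc$region_id), 0:(n - 1L))) {
    stop("region_ids must be unique and contiguous from 0", call. = FALSE)
  }
  hm <- parc$homolog_id[match(0:(n - 1L), parc$region_id)]
  if (any(hm[hm + 1L] != 0:(n - 1L))) {
    stop("homolog mapping is not symmetric", call. = FALSE)
  }
  hemi <- parc$hemisphere[match(0:(n - 1L), parc$region_id)]
  if (any(hemi == hemi[hm + 1L])) {
    stop("homolog pairs must cross hemispheres", call. = FALSE)
  }
  if (any(parc$volume <= 0)) stop("volumes must be positive", call. = FALSE)
  invisible(TRUE)
}

# Index (1-based row i, row j) of the homotopic pairs of a parcellation,
# in canonical i < j order.
homotopic_pairs <- function(parc) {
  ord <- match(0:(nrow(parc) - 1L), parc$region_id)
  hm <- parc$homolog_id[ord] + 1L
  i <- seq_len(nrow(parc))
  keep <- i < hm
  cbind(i = i[keep], j = hm[keep])
}

#' Generate a ground-truth structural graph with planted hubs
#'
#' Constructs a symmetric weighted graph at a requested binary density. When
#' `homotopic_guarantee` is set every homotopic pair is connected. `n_hubs`
#' designated nodes are wired to enough random partners that each hub's
#' degree is at least twice the mean degree of the non-hub nodes; remaining
#' edges are placed uniformly among pairs not touching a hub. Edge weights
#' are log-normal.
#'
#' @param parcellation A parcellation table.
#' @param density Target binary density in (0, 1].
#' @param n_hubs Number of planted hub nodes (0 for none).
#' @param homotopic_guarantee Logical; force all homotopic edges present.
#' @param seed Integer seed.
#' @return A `structural_truth` list with `weights` (N x N symmetric,
#'   zero diagonal), `hub_nodes` (0-based region ids) and `density`.
#' @export
generate_structural_truth <- function(parcellation, density, n_hubs = 0L,
                                      homotopic_guarantee = TRUE, seed = 1L) {
  validate_parcellation(parcellation)
  if (density <= 0 || density > 1) {
    stop("`density` must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(parcellation)
  n_possible <- n * (n - 1L) / 2L
  e_target <- round(density * n_possible)
  with_local_seed(seed, {
    adj <- matrix(0L, n, n)
    if (homotopic_guarantee) {
      hp <- homotopic_pairs(parcellation)
      adj[hp] <- 1L
      adj[hp[, c(2, 1), drop = FALSE]] <- 1L
    }
    hubs <- integer(0)
    if (n_hubs > 0L) {
      if (e_target >= n_possible) {
        stop("infeasible configuration: hubs cannot exceed twice the ",
             "non-hub mean degree in a (near-)complete graph", call. = FALSE)
      }
      hubs <- sort(sample.int(n, n_hubs)) # 1-based node indices
      # Hub target degree: k_h * (N - H) >= 2 * (2E - H * k_h) solved for
      # k_h gives 4E / (N + H); 15% margin absorbs fill-edge placement.
      k_hub <- min(n - 1L, ceiling(1.15 * 4 * e_target / (n + n_hubs)))
      for (h in hubs) {
        deficit <- k_hub - sum(adj[h, ])
        if (deficit > 0L) {
          cand <- setdiff(which(adj[h, ] == 0L), c(h, hubs))
          if (length(cand) < deficit) cand <- setdiff(which(adj[h, ] == 0L), h)
          if (length(cand) < deficit) {
            stop("infeasible configuration: cannot reach hub degree ", k_hub,
                 call. = FALSE)
          }
          pick <- sample(cand, deficit)
          adj[h, pick] <- 1L
          adj[pick, h] <- 1L
        }
      }
    }
    e_now <- sum(adj) / 2L
    if (e_now > e_target) {
      stop("infeasible configuration: homotopic and hub constraints require ",
           e_now, " edges but density allows only ", e_target, call. = FALSE)
    }
    # Fill to target among pairs avoiding hubs so hub dominance is preserved.
    ei <- edge_index(n)
    open <- adj[ei] == 0L
    no_hub <- !(ei[, 1] %in% hubs) & !(ei[, 2] %in% hubs)
    pool <- which(open & no_hub)
    need <- e_target - e_now
    if (length(pool) < need) pool <- which(open)
    if (length(pool) < need) {
      stop("infeasible configuration: not enough free pairs", call. = FALSE)
    }
    pick <- if (need > 0L) sample(pool, need) else integer(0)
    adj[ei[pick, , drop = FALSE]] <- 1L
    adj[ei[pick, c(2, 1), drop = FALSE]] <- 1L

    w <- matrix(0, n, n)
    on <- which(upper.tri(adj) & adj == 1L)
    w[on] <- rlnorm(length(on), meanlog = 0, sdlog = 0.6)
    w <- w + t(w)
    structure(
      list(weights = w, hub_nodes = hubs - 1L, density = density,
           n_edges = sum(adj) / 2L),
      class = "structural_truth"
    )
  })
}

# Eigenvalue-clipping nearest positive-definite repair: clip eigenvalues at
# `floor`, reconstruct, and rescale back to unit diagonal. Naive composition
# of coupling + homotopic + state terms can break positive-definiteness.
nearest_pd_correlation <- function(m, floor = 1e-8) {
  es <- eigen(m, symmetric = TRUE)
  vals <- pmax(es$values, floor)
  out <- es$vectors %*% (vals * t(es$vectors))
  stats::cov2cor((out + t(out)) / 2)
}

#' Assemble a full generative ground truth
#'
#' Combines a structural graph with the parameters of the hidden-Markov
#' covariance-switching signal model and precomputes the per-state
#' correlation matrices. The state correlation for regions i, j is
#' `coupling_gain * w(i,j)/max(w)` plus `homotopic_boost` for homotopic
#' pairs (a shared component present in every state, making homotopic
#' coupling both strong and temporally stable), plus a mean-zero,
#' state-specific deviation (equally spaced phases of two random-sign
#' reconfiguration patterns, giving every edge the same state-induced
#' variance) damped in proportion to structural weight and absent on
#' homotopic pairs — so structurally supported edges fluctuate less across
#' states. Each composed matrix is repaired to the
#' nearest unit-diagonal positive-definite correlation by eigenvalue
#' clipping.
#'
#' @param parcellation A parcellation table.
#' @param structural A `structural_truth`; built from `density`/`n_hubs`
#'   when omitted.
#' @param density,n_hubs Used only when `structural` is missing.
#' @param n_states Number of latent covariance states K.
#' @param state_dwell_mean Mean dwell time of a state, in samples.
#' @param homotopic_boost Added correlation for homotopic pairs.
#' @param coupling_gain Gain of the concave map from normalized structural
#'   weight to correlation.
#' @param background Shared global-signal correlation added between all
#'   region pairs (rank-one component).
#' @param state_scale Scale of the state-specific covariance deviations.
#' @param noise_sd Standard deviation of i.i.d. observation noise.
#' @param seed Integer seed.
#' @return A `ground_truth` list including `state_correlations`.
#' @export
make_ground_truth <- function(parcellation, structural = NULL,
                              density = 0.21, n_hubs = 4L,
                              n_states = 3L, state_dwell_mean = 150,
                              homotopic_boost = 0.25, coupling_gain = 0.65,
                              background = 0.2, state_scale = 0.25,
                              noise_sd = 0.3, seed = 1L) {
  validate_parcellation(parcellation)
  if (is.null(structural)) {
    structural <- generate_structural_truth(
      parcellation, density = density, n_hubs = n_hubs,
      homotopic_guarantee = TRUE, seed = derive_seed(seed, 11L)
    )
  }
  n <- nrow(parcellation)
  w <- structural$weights
  wn <- if (max(w) > 0) w / max(w) else w
  hp <- homotopic_pairs(parcellation)
  homo <- matrix(FALSE, n, n)
  homo[hp] <- TRUE
  homo[hp[, c(2, 1), drop = FALSE]] <- TRUE

  # Global-signal background (rank-one, PSD) plus a concave monotone map
  # from normalized weight to correlation: weakly weighted structural
  # connections still carry substantial coupling, as tract-weight/FC
  # relationships are compressive.
  base <- background + coupling_gain * wn^0.3
  base[homo] <- base[homo] + homotopic_boost
  diag(base) <- 0

  with_local_seed(derive_seed(seed, 29L), {
    states <- vector("list", n_states)
    if (n_states >= 2L) {
      # Fixed-amplitude phase rotation: states are equally spaced phases of
      # two random-sign reconfiguration patterns, delta_k = A cos(theta_k) +
      # B sin(theta_k). The deviations average to ~zero across states and
      # every edge receives the same state-induced variance, so temporal
      # variability differences downstream are carried by the damping terms
      # (structural weight, homotopic stability), not by pattern luck.
      amp <- state_scale / sqrt(2)
      sign_mat <- function() {
        s <- matrix_from_upper(sample(c(-1, 1), n * (n - 1L) / 2L,
                                      replace = TRUE), n)
        s
      }
      a_pat <- amp * sign_mat()
      b_pat <- amp * sign_mat()
      theta <- 2 * pi * (seq_len(n_states) - 1L) / n_states
      damp <- (1 - wn)
      damp[homo] <- 0
      for (k in seq_len(n_states)) {
        dev_k <- a_pat * cos(theta[k]) + b_pat * sin(theta[k])
        ck <- base + dev_k * damp
        ck <- pmin(pmax(ck, -0.9), 0.9)
        diag(ck) <- 1
        states[[k]] <- nearest_pd_correlation(ck)
      }
    } else {
      c1 <- pmin(pmax(base, -0.9), 0.9)
      diag(c1) <- 1
      states[[1L]] <- nearest_pd_correlation(c1)
    }
    structure(
      list(structural_weights = w, hub_nodes = structural$hub_nodes,
           state_correlations = states, n_states = n_states,
           state_dwell_mean = state_dwell_mean,
           homotopic_boost = homotopic_boost, coupling_gain = coupling_gain,
           background = background, state_scale = state_scale,
           noise_sd = noise_sd),
      class = "ground_truth"
    )
  })
}

#' Analytic state-averaged correlation of a ground truth
#'
#' Mean of the per-state correlation matrices — the long-run expectation the
#' simulated sample correlation converges to (before observation noise).
#'
#' @param truth A `ground_truth`.
#' @return Symmetric N x N matrix.
#' @export
state_mean_correlation <- function(truth) {
  Reduce(`+`, truth$state_correlations) / length(truth$state_correlations)
}

#' Default synthetic preset
#'
#' The reference configuration used by the package's own validation runs:
#' 20 homologous pairs (N = 40), structural density 0.21 with 4 planted
#' hubs, K = 3 latent states with mean dwell 150 samples, and a 0.645 s
#' sampling interval. Small enough for routine testing, large enough for
#' stable windowed correlation estimates.
#'
#' @param seed Integer seed.
#' @param n_pairs,density,n_hubs,n_states,state_dwell_mean Preset knobs,
#'   overridable for experiments.
#' @param ... Passed on to [make_ground_truth()].
#' @return List with elements `parcellation` and `truth`.
#' @export
default_preset <- function(seed = 1L, n_pairs = 20L, density = 0.21,
                           n_hubs = 4L, n_states = 3L,
                           state_dwell_mean = 150, ...) {
  parc <- generate_parcellation(n_pairs, seed = derive_seed(seed, 3L))
  truth <- make_ground_truth(
    parc, density = density, n_hubs = n_hubs, n_states = n_states,
    state_dwell_mean = state_dwell_mean, seed = derive_seed(seed, 7L), ...
  )
  list(parcellation = parc, truth = truth)
}

#' Simulate a streamline-count matrix from a structural ground truth
#'
#' Counts for a connected pair are Poisson with mean
#' `scale * weight(i,j) * mean(volume_i, volume_j)`; pairs with zero
#' structural weight get zero counts. The matrix is symmetric with a zero
#' diagonal (one draw per unordered pair).
#'
#' @param truth A `ground_truth` (or `structural_truth`) on `parcellation`.
#' @param parcellation The matching parcellation.
#' @param scale Positive rate multiplier.
#' @param seed Integer seed.
#' @return N x N nonnegative integer matrix.
#' @export
simulate_streamline_counts <- function(truth, parcellation, scale = 10,
                                       seed = 1L) {
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  validate_parcellation(parcellation)
  w <- if (inherits(truth, "ground_truth")) truth$structural_weights
       else truth$weights
  n <- nrow(parcellation)
  stopifnot(nrow(w) == n)
  vol <- parcellation$volume[match(0:(n - 1L), parcellation$region_id)]
  vmean <- outer(vol, vol, function(a, b) (a + b) / 2)
  lambda <- scale * w * vmean
  with_local_seed(seed, {
    up <- upper_values(lambda)
    counts <- integer(length(up))
    pos <- up > 0
    counts[pos] <- rpois(sum(pos), up[pos])
    matrix_from_upper(counts, n)
  })
}

#' Simulate state-switching BOLD-like regional time series
#'
#' A hidden state sequence follows a K-state Markov chain whose self-
#' transition probability is `1 - 1/state_dwell_mean` (geometric dwell with
#' the requested mean). Within a state, samples are zero-mean multivariate
#' Gaussian with that state's correlation matrix; i.i.d. Gaussian
#' observation noise of sd `noise_sd` is then added. The realized state
#' sequence is returned for diagnostics.
#'
#' @param truth A `ground_truth`.
#' @param parcellation The matching parcellation.
#' @param n_timepoints Number of samples T (>= 2).
#' @param sampling_interval Sampling interval in seconds (TR).
#' @param seed Integer seed.
#' @param subject_id Label attached to the series.
#' @return A `regional_ts` list: `values` (T x N, columns named by region
#'   id), `sampling_interval`, `subject_id`, `states` (length-T integer).
#' @export
simulate_bold <- function(truth, parcellation, n_timepoints = 2000L,
                          sampling_interval = 0.645, seed = 1L,
                          subject_id = "synthetic") {
  validate_parcellation(parcellation)
  if (n_timepoints < 2L) stop("`n_timepoints` must be >= 2", call. = FALSE)
  n <- nrow(parcellation)
  k <- truth$n_states
  chols <- vector("list", k)
  for (s in seq_len(k)) {
    ch <- tryCatch(chol(truth$state_correlations[[s]]), error = function(e) e)
    if (inherits(ch, "error")) {
      stop("generation failure: state ", s,
           " correlation matrix is not positive definite", call. = FALSE)
    }
    chols[[s]] <- ch
  }
  with_local_seed(seed, {
    stay <- max(0, 1 - 1 / truth$state_dwell_mean)
    states <- integer(n_timepoints)
    states[1L] <- sample.int(k, 1L)
    if (k > 1L) {
      u <- runif(n_timepoints - 1L)
      for (t in 2:n_timepoints) {
        if (u[t - 1L] < stay) {
          states[t] <- states[t - 1L]
        } else {
          others <- setdiff(seq_len(k), states[t - 1L])
          states[t] <- others[sample.int(length(others), 1L)]
        }
      }
    } else {
      states[] <- 1L
    }
    z <- matrix(rnorm(n_timepoints * n), n_timepoints, n)
    x <- matrix(0, n_timepoints, n)
    for (s in seq_len(k)) {
      idx <- which(states == s)
      if (length(idx)) x[idx, ] <- z[idx, , drop = FALSE] %*% chols[[s]]
    }
    x <- x + matrix(rnorm(n_timepoints * n, sd = truth$noise_sd),
                    n_timepoints, n)
    colnames(x) <- as.character(parcellation$region_id[
      match(0:(n - 1L), parcellation$region_id)])
    structure(
      list(values = x, sampling_interval = sampling_interval,
           subject_id = subject_id, states = states),
      class = "regional_ts"
    )
  })
}
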