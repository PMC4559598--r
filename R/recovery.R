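#' Planted-effect recovery run on the default synthetic preset
#'
#' Executes the full analysis on one synthetic subject (plus a small
#' synthetic cohort for the structural stages) generated from the default
#' preset, and collects every quantity the generator plants: homotopic
#' versus heterotopic strength and variability, small-worldness across
#' windows, structural-presence effects on edge statistics, SC-strength
#' coupling after Gaussian resampling, hub recovery, and the nodal
#' structure-function correlations. This is the package's end-to-end
#' validation surface; the summary it returns is what the acceptance
#' script reports.
#'
#' @param seed Master seed.
#' @param n_pairs,n_timepoints Preset sizes (defaults N = 40, T = 2000).
#' @param window_seconds,sampling_interval Window scheme (defaults 100 s at
#'   TR 0.645 s, i.e. 155 samples).
#' @param topology_step Window step for the per-window topology stage.
#' @param n_rand Null networks per window.
#' @param n_perm Permutations for the label-shuffling tests.
#' @param n_subjects Cohort size for the structural backbone and hub
#'   profile.
#' @return Named list of recovery statistics (see source for fields).
#' @export
planted_effect_summary <- function(seed = 1L, n_pairs = 20L,
                                   n_timepoints = 2000L,
                                   window_seconds = 100,
                                   sampling_interval = 0.645,
                                   topology_step = 20L, n_rand = 100L,
                                   n_perm = 10000L, n_subjects = 8L) {
  preset <- default_preset(seed = seed, n_pairs = n_pairs)
  parc <- preset$parcellation
  truth <- preset$truth
  n <- nrow(parc)
  hubs <- truth$hub_nodes + 1L # 1-based

  ts <- simulate_bold(truth, parc, n_timepoints, sampling_interval,
                      seed = derive_seed(seed, 101L))
  spec <- window_spec_seconds(window_seconds, sampling_interval, 1L)
  dfc <- sliding_window_dfc(ts, spec)
  sim <- spatial_similarity(static_fc(ts), dfc)
  es <- temporal_edge_stats(dfc)
  categories <- classify_edges(parc)

  cat_strength <- category_comparison(es$strength, categories, n_perm,
                                      seed = derive_seed(seed, 301L))
  cat_var <- category_comparison(es$variability, categories, n_perm,
                                 seed = derive_seed(seed, 401L))
  hh <- function(df) df[df$category_a == "homotopic" &
                          df$category_b == "heterotopic", ]

  topo_spec <- window_spec_seconds(window_seconds, sampling_interval,
                                   topology_step)
  topo_dfc <- sliding_window_dfc(ts, topo_spec)
  ms <- metric_time_series(topo_dfc, threshold_policy(), n_rand = n_rand,
                           seed = derive_seed(seed, 501L))

  # hub persistence at the full window resolution (no nulls needed)
  deg <- matrix(NA_integer_, dfc$n_windows, n)
  for (t in seq_len(dfc$n_windows)) {
    deg[t, ] <- degree_centrality(binarize(dfc$r[, , t], threshold_policy(),
                                           n_samples = spec$length))
  }
  fhub <- hub_persistence(deg)

  # structural cohort
  counts_list <- lapply(seq_len(n_subjects), function(s) {
    simulate_streamline_counts(truth, parc,
                               seed = derive_seed(seed, 200L + s))
  })
  sc_list <- lapply(seq_len(n_subjects), function(s) {
    sc_from_streamlines(counts_list[[s]], parc,
                        subject_id = sprintf("sub%02d", s))
  })
  backbone <- group_backbone(sc_list)
  sc_hubs <- structural_hub_profile(sc_list)

  sc1 <- sc_list[[1L]]
  presence <- sc_presence_test(es, sc1, n_perm,
                               seed = derive_seed(seed, 601L))
  coupling <- sc_strength_coupling(es, sc1, resample = TRUE)

  nodal_hub <- nodal_coupling(fhub$degree_tvar, sc_hubs$probability)
  nodal_deg <- nodal_coupling(fhub$degree_tvar, sc_hubs$mean_degree)
  func_hub_tvar <- nodal_coupling(fhub$degree_tvar, fhub$probability)

  list(
    n_regions = n,
    n_windows = dfc$n_windows,
    mean_similarity = mean(sim),
    homotopic_minus_heterotopic_strength = hh(cat_strength)$observed_diff,
    p_homotopic_strength = hh(cat_strength)$p_adjusted,
    homotopic_minus_heterotopic_variability = hh(cat_var)$observed_diff,
    p_homotopic_variability = hh(cat_var)$p_adjusted,
    sigma_min = min(ms$global$sigma),
    sigma_mean = mean(ms$global$sigma),
    sparsity_mean = mean(ms$global$sparsity),
    sc_present_strength_diff =
      presence$observed_diff[presence$statistic == "strength"],
    p_sc_present_strength =
      presence$p_value[presence$statistic == "strength"],
    sc_present_variability_diff =
      presence$observed_diff[presence$statistic == "variability"],
    p_sc_present_variability =
      presence$p_value[presence$statistic == "variability"],
    r_strength_sc = coupling$r_strength_sc,
    p_strength_sc = coupling$p_strength_sc,
    r_variability_sc = coupling$r_variability_sc,
    p_variability_sc = coupling$p_variability_sc,
    n_edges_sc_present = coupling$n_edges_sc_present,
    hub_prob_planted = mean(fhub$probability[hubs]),
    hub_prob_other = mean(fhub$probability[-hubs]),
    structural_hub_prob_planted = mean(sc_hubs$probability[hubs]),
    structural_hub_prob_other = mean(sc_hubs$probability[-hubs]),
    backbone_density = graph_sparsity((backbone$weights > 0) * 1),
    rho_functional_hub_prob_degree_tvar = func_hub_tvar$rho,
    rho_structural_hub_prob_func_tvar = nodal_hub$rho,
    p_structural_hub_prob_func_tvar = nodal_hub$p,
    rho_structural_degree_func_tvar = nodal_deg$rho,
    p_structural_degree_func_tvar = nodal_deg$p
  )
}
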