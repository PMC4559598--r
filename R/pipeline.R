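#' Run configuration
#'
#' Assembles and validates the parameters of an end-to-end run. Inputs can
#' be file paths (parcellation, per-subject time series, per-subject
#' streamline counts) or, when `n_pairs`/`n_subjects` are given instead,
#' the synthetic generator supplies them. Serializes to YAML and round
#' trips losslessly.
#'
#' @param parcellation_path,timeseries_paths,streamline_paths Optional
#'   input files; `timeseries_paths` and `streamline_paths` are character
#'   vectors with one entry per subject.
#' @param n_pairs,n_timepoints,n_subjects,n_hubs Synthetic-run sizes, used
#'   when no input files are given.
#' @param window_seconds Sliding-window length in seconds (the reference
#'   analysis uses 100; 50 and 150 are the standard sensitivity settings).
#' @param step_samples Window step for edge-level statistics.
#' @param topology_step_samples Window step for the per-window topology
#'   stage (which carries a null ensemble per window and is the expensive
#'   part).
#' @param sampling_interval TR in seconds.
#' @param threshold_mode,alpha_corr,target_sparsity Thresholding policy.
#' @param weighted Also compute weighted-network metrics.
#' @param variability `"var"` or `"std"`.
#' @param n_perm Permutations for all permutation tests.
#' @param n_rand Null networks per window.
#' @param swaps_per_edge Rewiring intensity.
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(parcellation_path = NULL, timeseries_paths = NULL,
                       streamline_paths = NULL,
                       n_pairs = 20L, n_timepoints = 2000L, n_subjects = 8L,
                       n_hubs = 4L,
                       window_seconds = 100, step_samples = 1L,
                       topology_step_samples = 20L,
                       sampling_interval = 0.645,
                       threshold_mode = "bonferroni_r", alpha_corr = 0.01,
                       target_sparsity = NULL, weighted = FALSE,
                       variability = "var", n_perm = 10000L, n_rand = 100L,
                       swaps_per_edge = 10L, seed = 1L,
                       out_dir = tempfile("dynconn_run_")) {
  for (p in c(parcellation_path, timeseries_paths, streamline_paths)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file does not exist: ", p, call. = FALSE)
    }
  }
  stopifnot(window_seconds > 0, step_samples >= 1, sampling_interval > 0,
            n_perm >= 100, n_rand >= 0, swaps_per_edge >= 1)
  cfg <- list(
    parcellation_path = parcellation_path,
    timeseries_paths = timeseries_paths,
    streamline_paths = streamline_paths,
    n_pairs = as.integer(n_pairs), n_timepoints = as.integer(n_timepoints),
    n_subjects = as.integer(n_subjects), n_hubs = as.integer(n_hubs),
    window_seconds = window_seconds, step_samples = as.integer(step_samples),
    topology_step_samples = as.integer(topology_step_samples),
    sampling_interval = sampling_interval,
    threshold_mode = threshold_mode, alpha_corr = alpha_corr,
    target_sparsity = target_sparsity, weighted = isTRUE(weighted),
    variability = variability, n_perm = as.integer(n_perm),
    n_rand = as.integer(n_rand), swaps_per_edge = as.integer(swaps_per_edge),
    seed = as.integer(seed), out_dir = out_dir
  )
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

config_policy <- function(cfg) {
  switch(cfg$threshold_mode,
    bonferroni_r = threshold_policy("bonferroni_r",
                                    alpha_corr = cfg$alpha_corr),
    sparsity = threshold_policy("sparsity",
                                target_sparsity = cfg$target_sparsity),
    fixed_r = threshold_policy("fixed_r", tau = cfg$alpha_corr),
    stop("unknown threshold mode: ", cfg$threshold_mode, call. = FALSE)
  )
}

#' Execute the full analysis pipeline
#'
#' Runs simulate/ingest, sliding-window connectivity, temporal edge
#' statistics, spatial-category tests, per-window topology with nulls, hub
#' persistence, structural-network construction with group backbone, and
#' structure-function coupling; writes every stage's outputs as TSV/JSON
#' under the configured directory and returns a manifest with per-output
#' checksums. Two runs with the same config and seed produce identical
#' manifests.
#'
#' @param cfg A [run_config()].
#' @return A `run_manifest` list (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }

  # --- ingest or simulate -------------------------------------------------
  if (!is.null(cfg$parcellation_path)) {
    parc <- load_parcellation(cfg$parcellation_path)
    ts_list <- lapply(cfg$timeseries_paths, load_timeseries)
    counts_list <- lapply(cfg$streamline_paths, load_matrix)
    truth <- NULL
  } else {
    preset <- default_preset(seed = cfg$seed, n_pairs = cfg$n_pairs,
                             n_hubs = cfg$n_hubs)
    parc <- preset$parcellation
    truth <- preset$truth
    ts_list <- lapply(seq_len(cfg$n_subjects), function(s) {
      simulate_bold(truth, parc, cfg$n_timepoints, cfg$sampling_interval,
                    seed = derive_seed(cfg$seed, 100L + s),
                    subject_id = sprintf("sub%02d", s))
    })
    counts_list <- lapply(seq_len(cfg$n_subjects), function(s) {
      simulate_streamline_counts(truth, parc,
                                 seed = derive_seed(cfg$seed, 200L + s))
    })
    emit("parcellation.tsv", function(p) save_parcellation(parc, p))
  }
  n_sub <- length(ts_list)
  policy <- config_policy(cfg)
  spec <- window_spec_seconds(cfg$window_seconds, cfg$sampling_interval,
                              cfg$step_samples)
  topo_spec <- window_spec_seconds(cfg$window_seconds,
                                   cfg$sampling_interval,
                                   cfg$topology_step_samples)
  categories <- classify_edges(parc)

  # --- functional stages, per subject ------------------------------------
  edge_stats_list <- vector("list", n_sub)
  tstats_list <- vector("list", n_sub)
  hub_list <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    ts <- ts_list[[s]]
    sid <- ts$subject_id
    dfc <- sliding_window_dfc(ts, spec)
    sim <- spatial_similarity(static_fc(ts), dfc)
    es <- temporal_edge_stats(dfc, cfg$variability)
    edge_stats_list[[s]] <- es
    emit(sprintf("%s_similarity.tsv", sid), function(p) {
      write.table(data.frame(window = seq_along(sim), onset = dfc$onsets,
                             similarity = sim),
                  p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    emit(sprintf("%s_strength.tsv", sid),
         function(p) save_matrix(es$strength, p))
    emit(sprintf("%s_variability.tsv", sid),
         function(p) save_matrix(es$variability, p))
    cat_strength <- category_comparison(es$strength, categories, cfg$n_perm,
                                        seed = derive_seed(cfg$seed,
                                                           300L + s))
    cat_var <- category_comparison(es$variability, categories, cfg$n_perm,
                                   seed = derive_seed(cfg$seed, 400L + s))
    emit(sprintf("%s_category_tests.tsv", sid), function(p) {
      write.table(rbind(cbind(statistic = "strength", cat_strength),
                        cbind(statistic = "variability", cat_var)),
                  p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    topo_dfc <- sliding_window_dfc(ts, topo_spec)
    ms <- metric_time_series(topo_dfc, policy, n_rand = cfg$n_rand,
                             swaps_per_edge = cfg$swaps_per_edge,
                             seed = derive_seed(cfg$seed, 500L + s))
    tstats_list[[s]] <- temporal_metric_stats(ms, cfg$variability)
    hub_list[[s]] <- hub_persistence(ms, variability = cfg$variability)
    emit(sprintf("%s_metrics.tsv", sid), function(p) {
      write.table(ms$global, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
    emit(sprintf("%s_hubs.tsv", sid), function(p) {
      write.table(hub_list[[s]], p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }

  # --- structural stages --------------------------------------------------
  coupling <- NULL
  if (length(counts_list) >= 2L) {
    sc_list <- lapply(seq_along(counts_list), function(s) {
      sc_from_streamlines(counts_list[[s]], parc,
                          subject_id = sprintf("sub%02d", s))
    })
    backbone <- group_backbone(sc_list)
    sc_hubs <- structural_hub_profile(sc_list)
    emit("backbone.tsv", function(p) save_matrix(backbone$weights, p))
    emit("backbone_p.tsv", function(p) save_matrix(backbone$p_values, p))
    emit("structural_hubs.tsv", function(p) {
      write.table(sc_hubs, p, sep = "\t", quote = FALSE, row.names = FALSE)
    })

    # group-level coupling on the backbone with group-mean edge stats
    n <- nrow(parc)
    mean_strength <- Reduce(`+`, lapply(edge_stats_list,
                                        `[[`, "strength")) / n_sub
    mean_var <- Reduce(`+`, lapply(edge_stats_list,
                                   `[[`, "variability")) / n_sub
    group_stats <- list(strength = mean_strength, variability = mean_var)
    coupling <- tryCatch({
      presence <- sc_presence_test(group_stats, backbone, cfg$n_perm,
                                   seed = derive_seed(cfg$seed, 600L))
      strength_coupling <- sc_strength_coupling(group_stats, backbone)
      func_tvar <- colMeans(do.call(rbind, lapply(hub_list,
                                                  `[[`, "degree_tvar")))
      nodal_hub <- nodal_coupling(func_tvar, sc_hubs$probability)
      nodal_deg <- nodal_coupling(func_tvar, sc_hubs$mean_degree)
      list(presence = presence,
           strength_coupling = unclass(strength_coupling),
           nodal_hub_probability = nodal_hub,
           nodal_degree = nodal_deg)
    }, error = function(e) {
      message("coupling stage skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(coupling)) {
      emit("coupling.json", function(p) {
        jsonlite::write_json(coupling, p, auto_unbox = TRUE, digits = NA)
      })
    }
  } else {
    message("structural inputs absent or singular; coupling stage skipped")
  }

  manifest <- list(
    config = unclass(cfg)[setdiff(names(cfg), "out_dir")],
    n_subjects = n_sub,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p)))
  )
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
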