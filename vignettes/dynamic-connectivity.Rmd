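---
title: "Dynamic functional brain networks and their structural constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional brain networks and their structural constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynconn)
```

## The analysis

Resting-state functional connectivity is not stationary: the correlation
structure between brain regions reorganizes on the scale of tens of
seconds. `dynconn` implements a complete sliding-window analysis of this
phenomenon together with its structural counterpart:

1. **Dynamic functional connectivity (D-FC).** For a regional time-series
   matrix (T samples x N regions), a rectangular window of length L is
   slid across the scan with step s, and the Pearson correlation matrix
   R_t of each window is retained, giving floor((T - L)/s) + 1 matrices.
   The reference scheme is a 100 s window (155 samples at TR = 0.645 s)
   and a one-sample step; 50 s and 150 s are the standard sensitivity
   settings. With an 883-sample scan this yields 729 windows.
2. **Temporal edge statistics.** Each edge's windowed correlation series
   r_t(i,j) is summarized by its temporal mean (strength) and its
   unbiased sample variance (variability). Both operate on raw r —
   negatives included — and reduce to one shared kernel
   (`temporal_stats()`), which is also applied to every global network
   metric and to nodal degree. Both variance and standard-deviation
   conventions appear in the literature, so both are
   available (`variability = "var"` or `"std"`); every sign-level
   conclusion is invariant to this monotone choice, and `"var"` is the
   default.
3. **Spatial similarity.** Each window's D-FC matrix is compared with the
   static (whole-scan) matrix by correlating their Fisher-z upper
   triangles. Fisher clipping (|r| capped at 1 - 1e-12) applies only
   here; edge statistics use raw r.
4. **Network construction.** An edge is retained when its correlation
   strictly exceeds a threshold. The default threshold inverts the
   two-sided Pearson test at a Bonferroni-corrected level
   (alpha_corr / (N(N-1)/2), df = L - 2); fixed-r and target-sparsity
   modes (top positive correlations, ties by descending r then ascending
   lexicographic pair) cover the sensitivity grid, and a weighted variant
   retains the correlation values. Negative correlations are always
   excluded. The per-edge test is two-sided by convention; a one-sided
   flag is available — the choice only shifts tau slightly.
5. **Topology.** Sparsity, clustering coefficient, characteristic path
   length, Newman degree assortativity, and nodal degree, with
   gamma/lambda/sigma/alpha-z normalization against 100 degree-preserving
   Maslov–Sneppen rewirings (10 attempted swaps per edge; the swap count
   is a convention, as no standard exists). Path length averages over
   connected pairs only, with the component census always reported —
   disconnected windows are rare in the intended regime but must not
   produce infinities. Nodes with degree < 2 contribute clustering 0, so
   Cp stays a mean over all N nodes. Assortativity of a regular graph is
   undefined and reported as NaN, excluded from summaries. Weighted
   metrics use Onnela clustering on max-normalized weights and Dijkstra
   path length with edge length 1/weight.
6. **Hubs.** Per window, a region is a hub when its degree strictly
   exceeds the mean degree; its persistence is the fraction of windows in
   which it qualifies, with "persistent" meaning strictly above 0.5.
7. **Structural networks.** Streamline counts are normalized by the mean
   volume of the two regions; a group backbone keeps edges whose presence
   across subjects rejects a one-tailed exact sign test at p < 0.05
   (zeros count as failures, which keeps the test exact), weighted by the
   across-subject mean including zeros (a nonzero-only mean is optional).
8. **Structure–function coupling.** At the connection level, edge
   strength/variability are compared between SC-present and SC-absent
   pairs by label permutation, and correlated with SC strength over the
   SC-present pairs after a rank-based inverse-normal transform
   ("Gaussian resampling") onto mean 0.5, sd 0.1 — rankit positions
   (rank - 0.5)/n with average ranks for ties; the plotting-position
   constant is a convention with no effect at sign level. Global topology
   couples across subjects; nodal coupling uses Spearman correlation
   because hub probabilities are discrete.

All permutation tests use the add-one estimator
p = (1 + #{|null| >= |obs|}) / (n_perm + 1), so p = 0 is impossible, and
category comparisons are Bonferroni-corrected by the fixed factor 3 (the
number of category pairs). Windows are left-aligned at onsets
0, s, 2s, ...; alignment is a convention the window-count closed form
makes explicit.

## The synthetic study

Real multiband fMRI/DTI inputs are out of scope, so the package carries a
generator whose outputs have the statistical structure the analysis
assumes, making every downstream stage testable end to end.

* **Parcellation**: 2 x n_pairs regions in homologous left/right pairs,
  log-normal volumes drawn per pair with small per-region jitter.
* **Structural truth**: a symmetric weighted graph at binary density 0.21
  (the empirical sparsity regime of adult structural networks), all
  homotopic pairs connected, and n_hubs planted hub nodes wired so each
  hub's degree is at least twice the non-hub mean; log-normal weights.
* **Signal model**: a hidden-Markov covariance-switching process. A
  K-state Markov chain (geometric dwell, mean 150 samples) selects among
  K correlation matrices; samples are zero-mean Gaussian within a state,
  plus i.i.d. observation noise (sd 0.3). Each state correlation is
  composed from four parts:
  * a rank-one global-signal background (0.2 between all pairs) — the
    broad positive offset characteristic of regional BOLD correlation
    matrices, which also keeps the composed matrix near positive
    definite;
  * structural coupling: `coupling_gain * (w / max(w))^0.3` — a concave
    monotone map, since tract-weight/FC relationships are compressive;
  * a homotopic boost (0.25) present in every state, so homotopic
    coupling is strong *and* temporally stable;
  * a state-specific deviation: two random-sign patterns A, B combined at
    equally spaced phases, `delta_k = A cos(theta_k) + B sin(theta_k)`,
    damped by (1 - w/max(w)) and zeroed on homotopic pairs. The phase
    construction gives every edge exactly the same state-induced variance
    and a zero across-state mean, so temporal-variability contrasts are
    carried by the *planted* damping (structural support, homotopic
    stability) rather than by pattern luck; with free random patterns the
    per-edge state variance is approximately chi-squared with ~2 degrees
    of freedom across edges, and that heterogeneity swamps the
    category contrasts at realistic sizes.
  Composition can still leave small negative eigenvalues, so each state
  matrix is repaired by eigenvalue clipping at 1e-8 and rescaled to unit
  diagonal.
* **Streamline counts**: Poisson with mean
  `scale * weight * mean(volume_i, volume_j)`, symmetric, zero off the
  structural skeleton — so normalizing by mean volume recovers
  `scale * weight` in expectation.

The default preset is N = 40 (20 pairs), K = 3 states, T = 2000 samples
at TR 0.645 s, 4 hubs, and an 8-subject cohort for the structural stages.
These sizes give stable windowed correlation estimates while keeping the
full run under a minute on one CPU. The calibration
(`coupling_gain = 0.65`, `background = 0.2`, `state_scale = 0.25`) was
chosen so the thresholded per-window networks occupy the empirically
reported sparsity regime (roughly 0.10-0.24 at the Bonferroni p < 0.01
threshold) with persistent small-world organization; it is fixed, not a
per-run tuning knob.

What the generator does *not* emulate: hemodynamics (no balloon model or
neural-mass dynamics), autocorrelated BOLD noise, spatial smoothness,
scanner drift, motion artifacts, or partial structural/functional hub
dissociation — in this model the planted structural hubs *are* the
functional hubs, so nodal structure–function correlations come out
positive, whereas empirical data with imperfect hub overlap can show the
opposite sign for structural degree versus functional degree variability.
Passing tests therefore demonstrate the correctness and sensitivity of
the analysis machinery under a controlled generative model, not claims
about any particular dataset.

## Numerical and design choices

* Window length in seconds converts to samples by `round(seconds / TR)`;
  100 s at 0.645 s is exactly 155 samples.
* Correlations are undefined for a region that is constant within a
  window; the pipeline fails fast naming the window and region rather
  than propagating NaN.
* The alpha-z normalization uses the sample (n - 1) standard deviation of
  the null assortativities; rewired nulls that are regular (NaN
  assortativity) are excluded from the null moments.
* Complete graphs admit no degree-preserving swap and are returned
  unchanged with a warning.
* Per-window null ensembles derive their seeds from one base seed plus
  the window index: reproducible, and uncorrelated across windows.
* All randomness flows through a per-call seeded generator that restores
  the caller's RNG state; identical calls are bit-identical.
* Histogram bin edges are shared across participants (explicit break
  vectors) so group-averaged normalized histograms remain normalized.
* The topology stage (metrics + 100 nulls per window) is the expensive
  part, so the orchestrator exposes a separate coarser window step for it
  (default 20 samples) while edge-level statistics use the one-sample
  step; both are configurable.

## Worked example

```{r example, eval = FALSE}
preset <- default_preset(seed = 1)
ts <- simulate_bold(preset$truth, preset$parcellation,
                    n_timepoints = 2000, sampling_interval = 0.645,
                    seed = 2)
spec <- window_spec_seconds(100, 0.645) # 155 samples, step 1
dfc <- sliding_window_dfc(ts, spec)
es <- temporal_edge_stats(dfc)
cats <- classify_edges(preset$parcellation)
category_comparison(es$strength, cats, n_perm = 10000, seed = 3)
```

The end-to-end validation surface is available as one call:

```{r recovery, eval = FALSE}
planted_effect_summary(seed = 1)
```

which regenerates the default study, runs every stage, and returns the
recovered contrasts, correlations, small-world indices and hub
probabilities. `run_pipeline(run_config(...))` performs the same stages
against files on disk and writes TSV/JSON outputs with a checksum
manifest.

## Limitations

* The generator's states are exchangeable covariance patterns; it makes
  no claim about the neural origin of connectivity dynamics (criticality,
  metastability, sampling variability of a static process, ...).
* Sliding-window correlation is the only D-FC estimator provided — no
  tapered windows, DCC/GARCH, or phase synchrony.
* Edge significance is Bonferroni-based; FDR and permutation-based edge
  selection are out of scope.
* Negative-correlation networks are excluded throughout, following the
  unresolved interpretation of negative BOLD coupling.
* Path length over connected pairs is one of several defensible
  conventions for fragmented graphs (harmonic means and component
  restrictions being alternatives); it is reported together with the
  component census so no fragmentation is hidden.
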