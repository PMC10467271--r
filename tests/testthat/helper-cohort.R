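# Shared fixture builders for cohort-level tests. Everything is generated
# in code under fixed seeds; no data files.

quiet_noise <- function() {
  p <- default_noise_params()
  p$cardiac_uM <- 0; p$resp_uM <- 0; p$mayer_uM <- 0; p$drift_uM <- 0
  p
}

# fast HbO-stage cohort: covariance-structured fluctuations + evoked
# response, no optics, no artifacts
hbo_cohort <- function(n_psd, n_nonpsd, effect_size, effect_states, seed,
                       rest_duration_s = 20) {
  simulate_cohort(n_psd = n_psd, n_nonpsd = n_nonpsd,
                  effect_size = effect_size, effect_states = effect_states,
                  rest_duration_s = rest_duration_s,
                  noise_params = quiet_noise(),
                  artifact_params = no_artifact_params(),
                  output_stage = "hbo", seed = seed)
}

# per-subject rest/task Fisher-z matrices of an HbO-stage cohort (no
# band-pass needed: the generator's fluctuations are already band-limited)
cohort_connectivity <- function(cohort) {
  out <- list()
  for (sub in cohort$subjects) {
    seg <- segment_states(sub$recording, sub$schedule)
    out[[sub$id]] <- list(
      rest = pearson_fisher(seg$rest, "rest", sub$id),
      task = pearson_fisher(seg$task, "task", sub$id))
  }
  out
}

# metric sweeps (optionally without the surrogate-normalized triple, and
# restricted to the states a test actually uses)
cohort_metric_sets <- function(connectivity, n_rand = 0, seed = 1,
                               states = c("rest", "task")) {
  ms <- list()
  for (k in seq_along(connectivity)) {
    id <- names(connectivity)[k]
    one <- list()
    for (s in states) {
      # near-null matrices can carry fewer positive weights than the
      # densest threshold requests; that warning is expected here
      one[[s]] <- suppressWarnings(
        metric_sweep(connectivity[[id]][[s]], n_rand = n_rand,
                     seed = seed + 2 * k + (s == "task")))
    }
    ms[[id]] <- one
  }
  ms
}
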