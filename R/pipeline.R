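#' Default end-to-end run configuration
#'
#' Bundles the cohort, preprocessing, network, statistics and classifier
#' settings of a full run with the study defaults: 19 PSD vs 18 non-PSD
#' subjects, 20-s rest baseline plus 360-s oddball task at 11 Hz, 0.5-s/6-SD
#' artifact rule, 0.01-0.2 Hz band, sparsity sweep 0.15-0.50 by 0.05 with
#' 100 rewired surrogates per threshold, uncorrected alpha 0.05 with
#' two-sided screening tests, and 8-fold cross-validation repeated 10 times.
#'
#' @param seed Master seed of the run.
#' @return Named list of class `fnirs_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    cohort = list(n_psd = 19, n_nonpsd = 18, effect_size = 1,
                  effect_states = c("rest", "task"),
                  rest_duration_s = 20, task_duration_s = 360,
                  output_stage = "intensity"),
    preprocess = list(window_s = 0.5, k_sd = 6, low_hz = 0.01, high_hz = 0.2,
                      order = 3, dpf = 6.0),
    network = list(sparsities = seq(0.15, 0.50, by = 0.05), n_rand = 100),
    stats = list(alpha = 0.05, tails = "two", fdr = FALSE),
    classifier = list(n_folds = 8, n_repeats = 10, variance_retained = 0.95,
                      cost_mode = "balanced", kernel = "linear"),
    seed = seed), class = "fnirs_config")
}

#' Run the full simulation-to-classification pipeline
#'
#' Executes, in order: cohort simulation (unless a cohort is supplied),
#' preprocessing to band-limited HbO, rest/task segmentation and Fisher-z
#' Pearson connectivity, the sparsity sweep with all graph metrics and their
#' AUCs, edge-wise and metric-wise group statistics, Spearman correlation of
#' every metric AUC with the pooled HAMD scores, and PSD/non-PSD
#' classification from the 79 AUC features of each state.
#'
#' @param config A [default_config()]-style list.
#' @param cohort Optional pre-built `fnirs_cohort` (simulated otherwise).
#' @param out_dir Optional output directory; when given, connectivity
#'   matrices, metric tables, statistics, classification reports and the
#'   archived configuration (with seed and content hash) are written there.
#' @param verbose Print stage progress.
#' @return An object of class `fnirs_analysis` with elements `manifest`,
#'   `connectivity`, `metric_sets`, `stats`, `classification`, `summary`
#'   and `config`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL,
                         out_dir = NULL, verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  t0 <- Sys.time()
  set.seed(config$seed)

  if (is.null(cohort)) {
    say("stage 1/6: simulating cohort")
    cohort <- simulate_cohort(
      n_psd = config$cohort$n_psd, n_nonpsd = config$cohort$n_nonpsd,
      effect_size = config$cohort$effect_size,
      effect_states = config$cohort$effect_states,
      rest_duration_s = config$cohort$rest_duration_s,
      task_duration_s = config$cohort$task_duration_s,
      output_stage = config$cohort$output_stage,
      seed = config$seed)
  }
  manifest <- cohort$manifest
  groups <- manifest$group

  say("stage 2/6: preprocessing")
  pp <- config$preprocess
  connectivity <- list()
  for (k in seq_along(cohort$subjects)) {
    sub <- cohort$subjects[[k]]
    res <- tryCatch(
      preprocess_recording(sub$recording, window_s = pp$window_s,
                           k_sd = pp$k_sd, low_hz = pp$low_hz,
                           high_hz = pp$high_hz, order = pp$order,
                           dpf = pp$dpf),
      error = function(e) stop("preprocess failed for subject ", sub$id,
                               ": ", conditionMessage(e)))
    seg <- segment_states(res$recording, sub$schedule)
    connectivity[[sub$id]] <- list(
      rest = pearson_fisher(seg$rest, state = "rest", subject_id = sub$id),
      task = pearson_fisher(seg$task, state = "task", subject_id = sub$id))
  }

  say("stage 3/6: graph metrics over the sparsity sweep")
  nw <- config$network
  metric_seeds <- sample.int(.Machine$integer.max - 1,
                             2 * length(connectivity))
  metric_sets <- list()
  for (k in seq_along(connectivity)) {
    id <- names(connectivity)[k]
    metric_sets[[id]] <- list(
      rest = metric_sweep(connectivity[[id]]$rest, nw$sparsities,
                          n_rand = nw$n_rand, seed = metric_seeds[2 * k - 1]),
      task = metric_sweep(connectivity[[id]]$task, nw$sparsities,
                          n_rand = nw$n_rand, seed = metric_seeds[2 * k]))
  }

  say("stage 4/6: group statistics")
  st <- config$stats
  is_psd <- groups == "PSD"
  edge_stats <- list()
  metric_stats <- list()
  spearman <- list()
  for (state in c("rest", "task")) {
    cms <- lapply(connectivity, `[[`, state)
    edge_stats[[state]] <- compare_connectivity_edges(
      cms[is_psd], cms[!is_psd], alpha = st$alpha, tails = st$tails,
      fdr = st$fdr)

    feats <- assemble_features(metric_sets, state = state, labels = groups)
    fx <- unclass(feats)
    recs <- lapply(colnames(fx), function(cn)
      compare_groups(fx[is_psd, cn], fx[!is_psd, cn], tails = st$tails,
                     alpha = st$alpha, name = cn))
    metric_stats[[state]] <- do.call(rbind, recs)

    rho <- t(vapply(colnames(fx), function(cn) {
      s <- spearman_vs_hamd(fx[, cn], manifest$hamd)
      c(rho = s$rho, p = s$p)
    }, numeric(2)))
    spearman[[state]] <- data.frame(metric = colnames(fx),
                                    rho = rho[, "rho"], p = rho[, "p"],
                                    significant = is.finite(rho[, "p"]) &
                                      rho[, "p"] < st$alpha,
                                    row.names = NULL)
  }

  say("stage 5/6: classification")
  cf <- config$classifier
  classification <- list()
  for (state in c("rest", "task")) {
    feats <- assemble_features(metric_sets, state = state, labels = groups)
    classification[[state]] <- fit_eval(
      feats, n_folds = cf$n_folds, n_repeats = cf$n_repeats,
      variance_retained = cf$variance_retained, cost_mode = cf$cost_mode,
      kernel = cf$kernel, seed = config$seed)
  }

  say("stage 6/6: summary")
  summary_df <- data.frame(
    state = c("rest", "task"),
    n_significant_edges = vapply(c("rest", "task"), function(s)
      nrow(edge_stats[[s]]$significant), integer(1)),
    n_significant_metrics = vapply(c("rest", "task"), function(s)
      sum(metric_stats[[s]]$significant), integer(1)),
    mean_accuracy = vapply(c("rest", "task"), function(s)
      classification[[s]]$mean_accuracy, numeric(1)),
    sd_accuracy = vapply(c("rest", "task"), function(s)
      classification[[s]]$sd_accuracy, numeric(1)),
    row.names = NULL)

  out <- structure(
    list(manifest = manifest, connectivity = connectivity,
         metric_sets = metric_sets,
         stats = list(edges = edge_stats, metrics = metric_stats,
                      spearman_hamd = spearman),
         classification = classification,
         summary = summary_df, config = config,
         elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "fnirs_analysis")

  if (!is.null(out_dir)) write_analysis(out, out_dir, cohort = cohort)
  out
}

# archive a run: config + seed + content hash, tabular outputs as CSV
write_analysis <- function(analysis, out_dir, cohort = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(analysis$config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stamp <- sprintf("config_md5=%s seed=%d", cfg_hash, analysis$config$seed)
  writeLines(stamp, file.path(out_dir, "RUNINFO.txt"))

  utils::write.csv(analysis$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  dir.create(file.path(out_dir, "connectivity"), showWarnings = FALSE)
  for (id in names(analysis$connectivity))
    for (state in c("rest", "task"))
      write_connectivity_csv(
        analysis$connectivity[[id]][[state]],
        file.path(out_dir, "connectivity",
                  sprintf("%s_%s.csv", id, state)))
  write_metrics_csv(analysis$metric_sets,
                    file.path(out_dir, "metrics_long.csv"))
  for (state in c("rest", "task")) {
    utils::write.csv(analysis$stats$edges[[state]]$records,
                     file.path(out_dir, sprintf("edge_stats_%s.csv", state)),
                     row.names = FALSE)
    utils::write.csv(analysis$stats$metrics[[state]],
                     file.path(out_dir, sprintf("metric_stats_%s.csv", state)),
                     row.names = FALSE)
    utils::write.csv(analysis$stats$spearman_hamd[[state]],
                     file.path(out_dir, sprintf("spearman_hamd_%s.csv", state)),
                     row.names = FALSE)
    rep <- analysis$classification[[state]]
    jsonlite::write_json(
      list(state = state, mean_accuracy = rep$mean_accuracy,
           sd_accuracy = rep$sd_accuracy,
           repeat_accuracy = rep$repeat_accuracy, config = rep$config),
      file.path(out_dir, sprintf("classification_%s.json", state)),
      auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(analysis$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.fnirs_analysis <- function(x, ...) {
  cat("fNIRS brain-network analysis\n")
  tb <- table(x$manifest$group)
  cat(sprintf("  cohort: %s\n",
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  s <- x$summary
  for (k in seq_len(nrow(s)))
    cat(sprintf("  %s: %d significant edges, %d significant metric AUCs, accuracy %.2f%% +/- %.2f%%\n",
                s$state[k], s$n_significant_edges[k],
                s$n_significant_metrics[k], 100 * s$mean_accuracy[k],
                100 * s$sd_accuracy[k]))
  invisible(x)
}

#' @export
summary.fnirs_analysis <- function(object, ...) {
  print(object)
  cat("\nTask-state significant edges:\n")
  sig <- object$stats$edges$task$significant
  if (nrow(sig)) print(sig[, c("name", "test", "p", "direction")])
  else cat("  none\n")
  cat("\nTask-state significant metric AUCs:\n")
  ms <- object$stats$metrics$task
  sigm <- ms[ms$significant, c("name", "test", "p", "direction")]
  if (nrow(sigm)) print(sigm) else cat("  none\n")
  invisible(object)
}
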