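# Plain-text subject container: <id>_timeseries.csv (time + channels, one
# column per channel/wavelength), <id>_stimuli.csv (onset_s, label) and
# <id>_meta.json (stage, rates, group, HAMD, montage, artifact log).
# Numeric columns are written with 17 significant digits so a write/read
# round trip reproduces the doubles exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a subject record to plain-text files
#'
#' @param subject A `subject_record`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_subject <- function(subject, dir) {
  stopifnot(inherits(subject, "subject_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- subject$recording
  n <- n_samples(rec)
  time_s <- (seq_len(n) - 1) / rec$fs_hz

  if (rec$stage == "hbo") {
    df <- data.frame(time_s = fmt_num(time_s))
    for (ch in seq_len(n_channels(rec)))
      df[[sprintf("ch%02d", ch)]] <- fmt_num(rec$data[ch, ])
  } else {
    df <- data.frame(time_s = fmt_num(time_s))
    for (w in seq_along(rec$wavelengths_nm))
      for (ch in seq_len(n_channels(rec)))
        df[[sprintf("ch%02d_%dnm", ch, rec$wavelengths_nm[w])]] <-
      fmt_num(rec$data[ch, , w])
  }
  f_data <- file.path(dir, paste0(subject$id, "_timeseries.csv"))
  utils::write.csv(df, f_data, row.names = FALSE, quote = FALSE)

  sched <- subject$schedule
  f_stim <- file.path(dir, paste0(subject$id, "_stimuli.csv"))
  utils::write.csv(
    data.frame(onset_s = fmt_num(sched$onsets_s), label = sched$labels),
    f_stim, row.names = FALSE, quote = FALSE)

  meta <- list(
    id = subject$id, group = subject$group, hamd = subject$hamd,
    stage = rec$stage, fs_hz = rec$fs_hz,
    wavelengths_nm = rec$wavelengths_nm,
    stim_duration_s = sched$stim_duration_s,
    rest_end_s = sched$rest_end_s, task_end_s = sched$task_end_s,
    units = list(time = "s", hemoglobin = "uM", frequency = "Hz"),
    artifact_log = subject$ground_truth$artifact_log,
    seed = subject$seed)
  f_meta <- file.path(dir, paste0(subject$id, "_meta.json"))
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA)
  invisible(c(f_data, f_stim, f_meta))
}

#' Read a subject record written by [write_subject()]
#'
#' @param dir Directory holding the three per-subject files.
#' @param id Subject identifier.
#' @return A `subject_record` (without simulation ground truth beyond the
#'   archived artifact log).
#' @export
read_subject <- function(dir, id) {
  f_data <- file.path(dir, paste0(id, "_timeseries.csv"))
  f_stim <- file.path(dir, paste0(id, "_stimuli.csv"))
  f_meta <- file.path(dir, paste0(id, "_meta.json"))
  for (f in c(f_data, f_stim, f_meta))
    if (!file.exists(f)) stop("missing subject file: ", f)

  meta <- tryCatch(jsonlite::read_json(f_meta, simplifyVector = TRUE),
                   error = function(e)
                     stop("malformed JSON metadata in ", f_meta, ": ",
                          conditionMessage(e)))
  need <- c("id", "group", "hamd", "stage", "fs_hz", "rest_end_s",
            "task_end_s")
  if (!all(need %in% names(meta)))
    stop("metadata in ", f_meta, " lacks field(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))

  df <- tryCatch(utils::read.csv(f_data, check.names = FALSE),
                 error = function(e)
                   stop("malformed timeseries CSV ", f_data, ": ",
                        conditionMessage(e)))
  if (!"time_s" %in% names(df) || ncol(df) < 2)
    stop("timeseries CSV ", f_data, " lacks time/channel columns")
  stim <- tryCatch(utils::read.csv(f_stim),
                   error = function(e)
                     stop("malformed stimulus CSV ", f_stim, ": ",
                          conditionMessage(e)))
  if (!all(c("onset_s", "label") %in% names(stim)))
    stop("stimulus CSV ", f_stim, " lacks onset_s/label columns")

  if (meta$stage == "hbo") {
    chcols <- grep("^ch[0-9]+$", names(df), value = TRUE)
    data <- t(as.matrix(df[, chcols, drop = FALSE]))
    dimnames(data) <- NULL
    rec <- optical_recording(data, stage = "hbo", fs_hz = meta$fs_hz)
  } else {
    wl <- as.numeric(meta$wavelengths_nm)
    nch <- length(grep(sprintf("_%dnm$", wl[1]), names(df)))
    if (nch < 1) stop("no channel columns for wavelength ", wl[1])
    data <- array(0, dim = c(nch, nrow(df), length(wl)))
    for (w in seq_along(wl))
      for (ch in seq_len(nch))
        data[ch, , w] <- df[[sprintf("ch%02d_%dnm", ch, wl[w])]]
    rec <- optical_recording(data, stage = meta$stage, fs_hz = meta$fs_hz,
                             wavelengths_nm = wl)
  }

  schedule <- structure(
    list(onsets_s = as.numeric(stim$onset_s),
         labels = as.character(stim$label),
         stim_duration_s = meta$stim_duration_s,
         rest_end_s = meta$rest_end_s, task_end_s = meta$task_end_s),
    class = "stimulus_schedule")

  art <- meta$artifact_log
  if (is.null(art) || !length(art))
    art <- data.frame(channel = integer(0), start_s = numeric(0),
                      end_s = numeric(0), kind = character(0))
  structure(
    list(id = meta$id, group = meta$group, hamd = as.integer(meta$hamd),
         recording = rec, schedule = schedule, montage = NULL,
         ground_truth = list(artifact_log = as.data.frame(art)),
         seed = meta$seed),
    class = "subject_record")
}

#' Write a connectivity matrix as labelled CSV
#' @param cm A `connectivity_matrix`.
#' @param path Output file.
#' @export
write_connectivity_csv <- function(cm, path) {
  z <- unclass(cm)
  lab <- sprintf("ch%02d", seq_len(nrow(z)))
  dimnames(z) <- list(lab, lab)
  utils::write.csv(z, path)
  invisible(path)
}

#' Write a binary network as an edge-list TSV
#'
#' Columns: `ch_i`, `ch_j`, `weight` (Fisher-z), `kept` (retained at the
#' network's sparsity).
#'
#' @param net A `binary_network`.
#' @param cm The `connectivity_matrix` it was derived from.
#' @param path Output file.
#' @export
write_edge_list_tsv <- function(net, cm, path) {
  z <- unclass(cm)
  n <- nrow(z)
  ut <- which(upper.tri(z), arr.ind = TRUE)
  df <- data.frame(ch_i = ut[, 1], ch_j = ut[, 2],
                   weight = z[ut], kept = net$adjacency[ut])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-subject metric sets as long-format CSV
#'
#' Columns: subject, state, scope (global/nodal), metric, channel (NA for
#' global), threshold (numeric or "AUC"), value.
#'
#' @param metric_sets Named list (subject) of lists with `rest`/`task`
#'   `metric_set`s.
#' @param path Output file.
#' @export
write_metrics_csv <- function(metric_sets, path) {
  rows <- list()
  for (id in names(metric_sets)) {
    for (state in names(metric_sets[[id]])) {
      ms <- metric_sets[[id]][[state]]
      if (is.null(ms)) next
      thr <- c(sprintf("%.2f", ms$sparsities), "AUC")
      gl <- cbind(ms$per_threshold$global, AUC = ms$auc$global)
      for (m in rownames(gl))
        rows[[length(rows) + 1]] <- data.frame(
          subject = id, state = state, scope = "global", metric = m,
          channel = NA_integer_, threshold = thr, value = gl[m, ],
          stringsAsFactors = FALSE)
      for (m in dimnames(ms$per_threshold$nodal)[[1]]) {
        nod <- rbind(t(ms$per_threshold$nodal[m, , ]), AUC = ms$auc$nodal[m, ])
        for (ch in seq_len(ncol(nod)))
          rows[[length(rows) + 1]] <- data.frame(
            subject = id, state = state, scope = "nodal", metric = m,
            channel = ch, threshold = thr, value = nod[, ch],
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
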