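#' Generate an auditory oddball stimulus schedule
#'
#' Builds the stimulus train of a classic auditory oddball run: a silent
#' rest baseline followed by a task block in which short tones are presented
#' with a jittered inter-stimulus interval. A fixed fraction of the tones are
#' rare "deviant" targets, the remainder frequent "standard" tones.
#'
#' Onsets are laid down sequentially from the end of the rest baseline; the
#' gap between consecutive onsets is the stimulus duration plus a uniform
#' draw from `isi_range_s`, so gaps always lie in
#' `stim_duration_s + isi_range_s`. The number of deviants is
#' `round(deviant_fraction * n)` exactly, with deviant positions shuffled by
#' the seeded RNG.
#'
#' @param task_duration_s Length of the stimulation block in seconds.
#' @param rest_duration_s Length of the pre-task rest baseline in seconds.
#' @param deviant_fraction Fraction of stimuli that are deviant targets.
#' @param isi_range_s Length-2 numeric, uniform jitter range (seconds) of the
#'   silent interval between consecutive stimuli.
#' @param stim_duration_s Duration of each tone in seconds.
#' @param seed Optional integer seed for reproducible schedules.
#'
#' @return An object of class `stimulus_schedule`: a list with `onsets_s`,
#'   `labels` (`"deviant"`/`"standard"`), `stim_duration_s`, `rest_end_s`
#'   and `task_end_s`.
#' @examples
#' sched <- generate_stimulus_schedule(seed = 1)
#' mean(sched$labels == "deviant")
#' @export
generate_stimulus_schedule <- function(task_duration_s = 360,
                                       rest_duration_s = 20,
                                       deviant_fraction = 0.25,
                                       isi_range_s = c(1, 3),
                                       stim_duration_s = 0.05,
                                       seed = NULL) {
  stopifnot(is.numeric(task_duration_s), task_duration_s > 0,
            is.numeric(rest_duration_s), rest_duration_s >= 0,
            deviant_fraction >= 0, deviant_fraction <= 1,
            length(isi_range_s) == 2, isi_range_s[1] >= 0,
            isi_range_s[1] <= isi_range_s[2],
            stim_duration_s > 0)
  if (!is.null(seed)) set.seed(seed)
  rest_end <- rest_duration_s
  task_end <- rest_duration_s + task_duration_s
  if (task_duration_s < stim_duration_s)
    stop("task block (", task_duration_s, " s) is too short to fit a single ",
         stim_duration_s, "-s stimulus")

  onsets <- numeric(0)
  t <- rest_end
  repeat {
    if (t + stim_duration_s > task_end) break
    onsets <- c(onsets, t)
    t <- t + stim_duration_s + stats::runif(1, isi_range_s[1], isi_range_s[2])
  }
  n <- length(onsets)
  if (n < 1)
    stop("infeasible packing: no stimulus fits in the task block")

  n_dev <- round(deviant_fraction * n)
  labels <- rep("standard", n)
  if (n_dev > 0) labels[sample.int(n, n_dev)] <- "deviant"

  structure(
    list(onsets_s = onsets,
         labels = labels,
         stim_duration_s = stim_duration_s,
         rest_end_s = rest_end,
         task_end_s = task_end),
    class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  n <- length(x$onsets_s)
  cat("Oddball stimulus schedule\n")
  cat(sprintf("  rest baseline: [0, %g) s; task: [%g, %g) s\n",
              x$rest_end_s, x$rest_end_s, x$task_end_s))
  cat(sprintf("  %d stimuli of %g s (%d deviant, %.1f%%)\n",
              n, x$stim_duration_s, sum(x$labels == "deviant"),
              100 * mean(x$labels == "deviant")))
  invisible(x)
}

#' Validate a stimulus schedule against its structural invariants
#'
#' Checks strict onset ordering, gap bounds, task-window containment and the
#' deviant count. Used by the generator's own tests and by file readers.
#'
#' @param sched A `stimulus_schedule`.
#' @param deviant_fraction Fraction the deviant count is checked against.
#' @param isi_range_s Jitter range the gaps are checked against.
#' @return `TRUE` invisibly; stops with an informative message otherwise.
#' @export
validate_stimulus_schedule <- function(sched, deviant_fraction = 0.25,
                                       isi_range_s = c(1, 3)) {
  stopifnot(inherits(sched, "stimulus_schedule"))
  on_s <- sched$onsets_s
  if (any(diff(on_s) <= 0)) stop("onsets not strictly increasing")
  gaps <- diff(on_s)
  lo <- sched$stim_duration_s + isi_range_s[1]
  hi <- sched$stim_duration_s + isi_range_s[2]
  if (length(gaps) && (min(gaps) < lo - 1e-9 || max(gaps) > hi + 1e-9))
    stop("inter-onset gaps outside [stim + isi_min, stim + isi_max]")
  if (any(on_s < sched$rest_end_s - 1e-9) ||
      any(on_s + sched$stim_duration_s > sched$task_end_s + 1e-9))
    stop("onsets outside the task window")
  n_dev <- sum(sched$labels == "deviant")
  if (n_dev != round(deviant_fraction * length(on_s)))
    stop("deviant count does not equal round(deviant_fraction * n)")
  invisible(TRUE)
}
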