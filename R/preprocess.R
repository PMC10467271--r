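#' Convert raw intensity to optical density
#'
#' Per channel and wavelength, `OD(t) = -log10(I(t) / I0)` where `I0` is the
#' mean intensity of that channel/wavelength over the whole recording
#' (optionally over the rest baseline only).
#'
#' @param rec An intensity-stage [optical_recording()].
#' @param baseline `"mean"` (whole recording, default) or `"rest"`.
#' @param schedule Required when `baseline = "rest"`.
#' @return An od-stage `optical_recording`.
#' @export
intensity_to_od <- function(rec, baseline = c("mean", "rest"),
                            schedule = NULL) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(rec, "optical_recording"))
  if (rec$stage != "intensity") stop("expected an intensity-stage recording")
  x <- rec$data
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at channel %d, sample %d",
                 bad[1], bad[2]))
  }
  idx <- seq_len(dim(x)[2])
  if (baseline == "rest") {
    if (is.null(schedule)) stop("baseline = 'rest' requires a schedule")
    idx <- which((idx - 1) / rec$fs_hz < schedule$rest_end_s)
    if (!length(idx)) stop("empty rest baseline")
  }
  od <- x
  for (w in seq_len(dim(x)[3])) {
    i0 <- rowMeans(x[, idx, w, drop = FALSE])
    od[, , w] <- -log10(x[, , w] / i0)
  }
  optical_recording(od, stage = "od", fs_hz = rec$fs_hz,
                    wavelengths_nm = rec$wavelengths_nm,
                    montage = rec$montage)
}

# sample index ranges of the consecutive non-overlapping detection windows;
# a trailing partial window of >= 2 samples is kept
window_bounds <- function(n, w) {
  starts <- seq(1L, n, by = w)
  ends <- pmin(starts + w - 1L, n)
  keep <- (ends - starts + 1L) >= 2L
  cbind(start = starts[keep], end = ends[keep])
}

#' Detect motion artifacts in optical-density data
#'
#' The recording is tiled into consecutive non-overlapping windows of
#' `round(window_s * fs)` samples. Per channel, a window is flagged when the
#' within-window range (max - min) of the OD signal exceeds `k_sd` times the
#' standard deviation of that channel's whole-trial OD, at any wavelength.
#'
#' @param rec An od-stage [optical_recording()].
#' @param window_s Window length in seconds (0.5 by default).
#' @param k_sd Range threshold in whole-trial SD multiples (6 by default).
#' @return An object of class `artifact_mask`: list with `flags`
#'   (channels x windows logical), `windows` (sample bounds), `window_s`,
#'   `k_sd` and `n_samples`.
#' @export
detect_motion_artifacts <- function(rec, window_s = 0.5, k_sd = 6) {
  stopifnot(inherits(rec, "optical_recording"))
  if (rec$stage != "od") stop("expected an od-stage recording")
  w <- round(window_s * rec$fs_hz)
  if (w < 2) stop("window_s x fs must span at least 2 samples")
  n <- n_samples(rec)
  nch <- n_channels(rec)
  nwl <- dim(rec$data)[3]
  bounds <- window_bounds(n, w)
  flags <- matrix(FALSE, nch, nrow(bounds))
  for (ch in seq_len(nch)) {
    for (wl in seq_len(nwl)) {
      x <- rec$data[ch, , wl]
      s <- stats::sd(x)
      if (s == 0) {
        warning("channel ", ch, " wavelength ", wl,
                " has zero variance; no windows flagged")
        next
      }
      thr <- k_sd * s
      for (b in seq_len(nrow(bounds))) {
        seg <- x[bounds[b, 1]:bounds[b, 2]]
        if (max(seg) - min(seg) > thr) flags[ch, b] <- TRUE
      }
    }
  }
  structure(list(flags = flags, windows = bounds, window_s = window_s,
                 k_sd = k_sd, n_samples = n),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("Artifact mask: %d/%d windows flagged (%.1f%%), %g-s windows, %gx SD rule\n",
              sum(x$flags), length(x$flags), 100 * mean(x$flags),
              x$window_s, x$k_sd))
  invisible(x)
}

# flagged sample indices of one channel
flagged_samples <- function(mask, ch) {
  b <- mask$windows[mask$flags[ch, ], , drop = FALSE]
  if (!nrow(b)) return(integer(0))
  sort(unique(unlist(lapply(seq_len(nrow(b)),
                            function(k) b[k, 1]:b[k, 2]))))
}

#' Reconstruct artifact-flagged samples by spline interpolation
#'
#' Samples inside flagged windows are discarded and re-estimated per channel
#' (and wavelength) by a natural cubic spline through all unflagged samples
#' of that channel. Flagged stretches at the recording edges, where the
#' spline would extrapolate, are filled with the nearest clean value and
#' noted in the `edge_extrapolated` attribute. Unflagged samples are passed
#' through unchanged.
#'
#' @param rec An od-stage [optical_recording()].
#' @param mask An `artifact_mask` from [detect_motion_artifacts()].
#' @return The corrected od-stage recording.
#' @export
correct_motion_artifacts <- function(rec, mask) {
  stopifnot(inherits(rec, "optical_recording"), inherits(mask, "artifact_mask"))
  if (rec$stage != "od") stop("expected an od-stage recording")
  if (nrow(mask$flags) != n_channels(rec) || mask$n_samples != n_samples(rec))
    stop("mask dimensions do not match the recording")
  out <- rec$data
  n <- n_samples(rec)
  edge_log <- character(0)
  for (ch in seq_len(n_channels(rec))) {
    bad <- flagged_samples(mask, ch)
    if (!length(bad)) next
    good <- setdiff(seq_len(n), bad)
    if (length(good) < 4)
      stop("channel ", ch, " is (almost) entirely flagged; cannot reconstruct")
    interior <- bad[bad > min(good) & bad < max(good)]
    edges <- setdiff(bad, interior)
    if (length(edges))
      edge_log <- c(edge_log, sprintf("channel %d: %d edge samples filled with nearest clean value",
                                      ch, length(edges)))
    for (wl in seq_len(dim(rec$data)[3])) {
      y <- rec$data[ch, , wl]
      if (length(interior))
        out[ch, interior, wl] <- stats::spline(good, y[good], xout = interior,
                                               method = "natural")$y
      if (length(edges)) {
        lo <- edges[edges < min(good)]
        hi <- edges[edges > max(good)]
        if (length(lo)) out[ch, lo, wl] <- y[min(good)]
        if (length(hi)) out[ch, hi, wl] <- y[max(good)]
      }
    }
  }
  res <- optical_recording(out, stage = "od", fs_hz = rec$fs_hz,
                           wavelengths_nm = rec$wavelengths_nm,
                           montage = rec$montage)
  attr(res, "edge_extrapolated") <- edge_log
  res
}

# zero-phase Butterworth band-pass of one series with odd-reflection padding
# to suppress edge transients
zerophase_bandpass <- function(x, fs, low_hz, high_hz, order = 3) {
  n <- length(x)
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  x <- x - mean(x)   # DC lies outside any passband; removing it up front
  p <- min(n - 1L, ceiling(fs / low_hz))  # kills the slow startup transient
  left <- 2 * x[1] - x[(p + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - p)]
  padded <- c(left, x, right)
  y <- signal::filtfilt(bf, padded)
  y[(p + 1):(p + n)]
}

#' Zero-phase band-pass filter
#'
#' Forward-backward Butterworth filtering (order `order` per pass, zero net
#' phase) of every channel (and wavelength) in the band `[low_hz, high_hz]`.
#' The default 0.01-0.2 Hz band isolates the slow hemodynamic fluctuations
#' and removes cardiac, respiratory and blood-pressure components.
#'
#' @param rec An od- or hbo-stage [optical_recording()].
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth order per pass.
#' @return The filtered recording at the same stage.
#' @export
bandpass <- function(rec, low_hz = 0.01, high_hz = 0.2, order = 3) {
  stopifnot(inherits(rec, "optical_recording"))
  if (rec$stage == "intensity")
    stop("band-pass applies to od or hbo stages, not raw intensity")
  fs <- rec$fs_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  n <- n_samples(rec)
  min_n <- 3 * ceiling(fs / low_hz)
  if (n < min_n)
    stop("recording too short for a ", low_hz, " Hz high-pass corner (need >= ",
         min_n, " samples, i.e. three periods of the low cutoff); ",
         "filter a longer segment")
  out <- rec$data
  if (rec$stage == "hbo") {
    for (ch in seq_len(n_channels(rec)))
      out[ch, ] <- zerophase_bandpass(rec$data[ch, ], fs, low_hz, high_hz, order)
  } else {
    for (ch in seq_len(n_channels(rec)))
      for (wl in seq_len(dim(rec$data)[3]))
        out[ch, , wl] <- zerophase_bandpass(rec$data[ch, , wl], fs,
                                            low_hz, high_hz, order)
  }
  optical_recording(out, stage = rec$stage, fs_hz = fs,
                    wavelengths_nm = rec$wavelengths_nm,
                    montage = rec$montage, hbr = rec$hbr)
}

#' Preprocess a raw recording to band-limited HbO
#'
#' Driver applying the stages in fixed order: optical-density conversion,
#' motion-artifact detection (0.5-s windows, 6x whole-trial SD) and spline
#' reconstruction, zero-phase 0.01-0.2 Hz band-pass, and modified
#' Beer-Lambert inversion to HbO/HbR. A recording already at the hbo stage
#' is only band-pass filtered.
#'
#' @param rec An [optical_recording()] at the intensity (or hbo) stage.
#' @param window_s,k_sd Artifact detection parameters.
#' @param low_hz,high_hz,order Band-pass parameters.
#' @param dpf Differential pathlength factor for the Beer-Lambert inversion.
#' @param baseline OD baseline convention, see [intensity_to_od()].
#' @param schedule Optional schedule (only used for `baseline = "rest"`).
#' @return List with `recording` (hbo stage), `mask` (the artifact mask, or
#'   `NULL` for hbo input) and `steps` (ordered character log of the stages
#'   applied).
#' @export
preprocess_recording <- function(rec, window_s = 0.5, k_sd = 6,
                                 low_hz = 0.01, high_hz = 0.2, order = 3,
                                 dpf = 6.0, baseline = "mean",
                                 schedule = NULL) {
  stopifnot(inherits(rec, "optical_recording"))
  steps <- character(0)
  mask <- NULL
  if (rec$stage == "hbo") {
    rec <- bandpass(rec, low_hz, high_hz, order)
    steps <- c(steps, "bandpass")
  } else {
    if (rec$stage == "intensity") {
      rec <- intensity_to_od(rec, baseline = baseline, schedule = schedule)
      steps <- c(steps, "intensity_to_od")
    }
    mask <- detect_motion_artifacts(rec, window_s = window_s, k_sd = k_sd)
    steps <- c(steps, "detect_motion_artifacts")
    rec <- correct_motion_artifacts(rec, mask)
    steps <- c(steps, "correct_motion_artifacts")
    rec <- bandpass(rec, low_hz, high_hz, order)
    steps <- c(steps, "bandpass")
    rec <- od_to_hemo(rec, dpf = dpf)
    steps <- c(steps, "od_to_hemo")
  }
  list(recording = rec, mask = mask, steps = steps)
}
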