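#' Default physiological noise parameters
#'
#' Amplitudes are micromolar HbO equivalents; frequencies in Hz. The cardiac
#' and respiratory components lie above the 0.01-0.2 Hz analysis band so the
#' band-pass stage demonstrably removes them; the Mayer-wave component lies
#' inside the band and is deliberately small. `sd_uM` is the standard
#' deviation of the band-limited hemodynamic background fluctuations whose
#' inter-channel covariance carries the planted group structure;
#' `lfo_band_hz` is their spectral support.
#'
#' @return Named list of noise parameters.
#' @export
default_noise_params <- function() {
  list(sd_uM = 0.5,
       lfo_band_hz = c(0.01, 0.2),
       cardiac_hz = 1.2, cardiac_uM = 0.15,
       resp_hz = 0.25, resp_uM = 0.10,
       mayer_hz = 0.10, mayer_uM = 0.03,
       drift_uM = 0.10,
       freq_jitter = 0.05)
}

#' Disabled noise parameters (deterministic forward model)
#' @return Noise parameter list with every stochastic component set to zero.
#' @export
no_noise_params <- function() {
  p <- default_noise_params()
  p$sd_uM <- 0; p$cardiac_uM <- 0; p$resp_uM <- 0; p$mayer_uM <- 0
  p$drift_uM <- 0
  p
}

#' Default motion-artifact injection parameters
#'
#' Artifact amplitudes are expressed as multiples of the clean whole-trial
#' optical-density standard deviation of the affected channel/wavelength, so
#' a `spike_k_sd = 10` spike is unambiguously above the 6-SD detection rule.
#'
#' @return Named list of artifact parameters.
#' @export
default_artifact_params <- function() {
  list(n_spikes = 2, n_shifts = 1,
       spike_k_sd = 10, spike_duration_s = 0.4,
       shift_k_sd = 8, shift_duration_s = c(3, 8))
}

#' No-artifact parameters
#' @return Artifact parameter list injecting nothing.
#' @export
no_artifact_params <- function() {
  p <- default_artifact_params()
  p$n_spikes <- 0L; p$n_shifts <- 0L
  p
}

#' Default hemodynamic response parameters
#'
#' Canonical double-gamma impulse response (peak 6 s, undershoot peaking near
#' 15 s with 1/6 relative amplitude), peak-normalized. Response amplitudes
#' are micromolar HbO at the peak for an isolated stimulus; deviant (target)
#' tones evoke the larger response.
#'
#' @return Named list with `peak_s`, `undershoot_ratio`, `amp_deviant_uM`,
#'   `amp_standard_uM`, `duration_s`.
#' @export
default_hrf_params <- function() {
  list(peak_s = 6, undershoot_ratio = 1 / 6,
       amp_deviant_uM = 0.8, amp_standard_uM = 0.4,
       duration_s = 30)
}

#' Canonical double-gamma hemodynamic response function
#'
#' @param t Time grid in seconds (t >= 0).
#' @param peak_s Time to peak of the positive lobe.
#' @param undershoot_ratio Relative amplitude of the late undershoot.
#' @return Peak-normalized HRF sampled at `t`.
#' @export
canonical_hrf <- function(t, peak_s = 6, undershoot_ratio = 1 / 6) {
  stopifnot(all(t >= 0))
  # gamma with rate 1 peaks at shape - 1
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = 16, rate = 1)
  h / max(h)
}

# Band-limited unit-variance Gaussian series by spectral synthesis: white
# noise is transformed to the frequency domain, bins outside [low, high] Hz
# are zeroed, and the retained power is rescaled to unit variance. Columns
# are independent; mixing with a Cholesky factor afterwards gives exactly
# the planted cross-channel covariance in expectation.
bandlimited_noise <- function(n, n_series, fs, band) {
  freqs <- (seq_len(n) - 1) * fs / n
  folded <- pmin(freqs, fs - freqs)
  keep <- folded >= band[1] & folded <= band[2]
  n_keep <- sum(keep)
  if (n_keep < 2) stop("band too narrow for the series length")
  scale <- sqrt(n / n_keep)
  f <- stats::mvfft(matrix(stats::rnorm(n * n_series), n, n_series))
  f[!keep, ] <- 0
  Re(stats::mvfft(f, inverse = TRUE)) / n * scale
}

# HRF-convolved stimulus regressor (length n, one channel's unit loading)
stimulus_regressor <- function(schedule, n, fs, hrf_params) {
  u <- numeric(n)
  idx <- pmin(pmax(round(schedule$onsets_s * fs) + 1L, 1L), n)
  amp <- ifelse(schedule$labels == "deviant",
                hrf_params$amp_deviant_uM, hrf_params$amp_standard_uM)
  for (k in seq_along(idx)) u[idx[k]] <- u[idx[k]] + amp[k]
  th <- seq(0, hrf_params$duration_s, by = 1 / fs)
  h <- canonical_hrf(th, hrf_params$peak_s, hrf_params$undershoot_ratio)
  full <- stats::convolve(u, rev(h), type = "open")
  full[seq_len(n)]
}

# spatial loading of the evoked response: mid-frontal channels respond most
channel_loadings <- function(n_channels) {
  i <- seq_len(n_channels)
  0.8 + 0.4 * exp(-((i - (n_channels + 1) / 2)^2) / 8)
}

#' Simulate one subject's oddball-task fNIRS recording
#'
#' Forward model with known ground truth. The HbO series of each channel is
#' the sum of (i) an HRF-convolved stimulus regressor scaled by a fixed
#' spatial loading, (ii) band-limited multivariate Gaussian fluctuations
#' whose covariance is the rest-state profile during the baseline and the
#' task-state profile during the task block, (iii) sinusoidal physiological
#' nuisance (cardiac, respiratory, Mayer waves) and a linear drift. HbR is
#' modeled as a scaled negative copy of the HbO ground truth plus small
#' independent fluctuations. Raw intensity is obtained per wavelength by the
#' forward modified Beer-Lambert law, with optional spike/shift motion
#' artifacts injected in optical-density space.
#'
#' @param id Subject identifier.
#' @param group `"PSD"` or `"nonPSD"`.
#' @param state_covariances List with `rest` and `task` channel covariance
#'   matrices (µM²), e.g. from [group_covariance_profiles()].
#' @param schedule A `stimulus_schedule`.
#' @param montage A `channel_montage`.
#' @param noise_params See [default_noise_params()].
#' @param artifact_params See [default_artifact_params()].
#' @param hrf_params See [default_hrf_params()].
#' @param seed Integer seed; the whole subject is a deterministic function
#'   of its arguments.
#' @param hamd Optional HAMD-24 depression score; drawn uniformly from the
#'   group-consistent integer range (PSD 8-25, nonPSD 0-7) when `NULL`.
#' @param output_stage `"intensity"` for the full forward model or `"hbo"`
#'   to stop at the noisy HbO stage (no optics, no artifacts).
#' @param dpf,i0 Differential pathlength factor and nominal source intensity
#'   of the forward optical model.
#' @return An object of class `subject_record`: list with `id`, `group`,
#'   `hamd`, `recording` (an [optical_recording()]), `schedule`, `montage`
#'   and `ground_truth` (true HbO/HbR, artifact log, regressor).
#' @export
generate_subject <- function(id, group = c("PSD", "nonPSD"),
                             state_covariances,
                             schedule = generate_stimulus_schedule(seed = seed),
                             montage = dlpfc_montage(),
                             noise_params = default_noise_params(),
                             artifact_params = default_artifact_params(),
                             hrf_params = default_hrf_params(),
                             seed = 1, hamd = NULL,
                             output_stage = c("intensity", "hbo"),
                             dpf = 6.0, i0 = 1000) {
  group <- match.arg(group)
  output_stage <- match.arg(output_stage)
  stopifnot(inherits(schedule, "stimulus_schedule"))
  set.seed(seed)

  fs <- 11
  nch <- nrow(montage$channels)
  cv_rest <- state_covariances$rest
  cv_task <- state_covariances$task
  if (is.null(cv_rest) || is.null(cv_task))
    stop("state_covariances must contain 'rest' and 'task'")
  if (nrow(cv_rest) != nch || nrow(cv_task) != nch)
    stop("covariance dimension does not match the channel count")

  n <- floor(schedule$task_end_s * fs)
  tgrid <- (seq_len(n) - 1) / fs
  rest_idx <- which(tgrid < schedule$rest_end_s)
  task_idx <- setdiff(seq_len(n), rest_idx)

  # evoked response (zero during rest by construction of the schedule)
  reg <- stimulus_regressor(schedule, n, fs, hrf_params)
  load <- channel_loadings(nch)
  signal_mat <- outer(load, reg)            # nch x n

  # band-limited covariance-structured fluctuations, spliced by state so the
  # rest segment carries the rest covariance and the task segment the task
  # covariance exactly
  noise_mat <- matrix(0, nch, n)
  if (noise_params$sd_uM > 0) {
    # Cholesky mixing at the covariance's own scale
    mix <- function(cv) {
      z <- bandlimited_noise(n, nch, fs, noise_params$lfo_band_hz)
      t(z %*% chol(cv + diag(1e-12, nch)))
    }
    strip <- function(m) { attributes(m) <- list(dim = dim(m)); m }
    if (identical(strip(cv_rest), strip(cv_task))) {
      # same covariance in both states: one stationary stream
      noise_mat <- mix(cv_task)
    } else {
      stream_rest <- mix(cv_rest)
      stream_task <- mix(cv_task)
      noise_mat[, rest_idx] <- stream_rest[, rest_idx]
      noise_mat[, task_idx] <- stream_task[, task_idx]
    }
  }

  hbo_truth <- signal_mat + noise_mat

  # physiological nuisance + drift (shared frequencies, per-channel phase)
  nuisance <- matrix(0, nch, n)
  jit <- function(f) f * (1 + noise_params$freq_jitter * stats::runif(1, -1, 1))
  for (comp in list(c(noise_params$cardiac_hz, noise_params$cardiac_uM),
                    c(noise_params$resp_hz, noise_params$resp_uM),
                    c(noise_params$mayer_hz, noise_params$mayer_uM))) {
    if (comp[2] > 0) {
      f <- jit(comp[1])
      ph <- stats::runif(nch, 0, 2 * pi)
      nuisance <- nuisance + comp[2] *
        sin(outer(ph, 2 * pi * f * tgrid, `+`))
    }
  }
  if (noise_params$drift_uM > 0) {
    slopes <- noise_params$drift_uM * stats::runif(nch, -1, 1)
    nuisance <- nuisance + outer(slopes, (tgrid - mean(tgrid)) / max(tgrid))
  }
  hbo_full <- hbo_truth + nuisance

  hbr <- -0.35 * hbo_truth
  if (noise_params$sd_uM > 0 && output_stage == "intensity")
    hbr <- hbr + t(bandlimited_noise(n, nch, fs,
                                     noise_params$lfo_band_hz)) * 0.05

  if (is.null(hamd)) {
    hamd <- if (group == "PSD") sample(8:25, 1) else sample(0:7, 1)
  }
  if (group == "PSD" && hamd < 8) stop("PSD subjects require HAMD >= 8")
  if (group == "nonPSD" && hamd >= 8) stop("nonPSD subjects require HAMD < 8")

  artifact_log <- data.frame(channel = integer(0), start_s = numeric(0),
                             end_s = numeric(0), kind = character(0),
                             stringsAsFactors = FALSE)

  if (output_stage == "hbo") {
    rec <- optical_recording(hbo_full, stage = "hbo", fs_hz = fs,
                             montage = montage, hbr = hbr)
  } else {
    ext <- extinction_coefficients()
    wl <- ext$wavelength_nm
    d_cm <- montage$distance_cm
    od <- array(0, dim = c(nch, n, length(wl)))
    for (w in seq_along(wl)) {
      od[, , w] <- (ext$eps_hbo[w] * hbo_full + ext$eps_hbr[w] * hbr) *
        1e-6 * d_cm * dpf
    }

    # motion artifacts in OD space, amplitude relative to each
    # channel/wavelength's clean trial SD; windows are non-overlapping and
    # confined to the recording span
    n_art <- artifact_params$n_spikes + artifact_params$n_shifts
    if (n_art > 0) {
      kinds <- c(rep("spike", artifact_params$n_spikes),
                 rep("shift", artifact_params$n_shifts))
      occupied <- matrix(numeric(0), ncol = 2)
      for (kind in kinds) {
        dur <- if (kind == "spike") artifact_params$spike_duration_s else
          stats::runif(1, artifact_params$shift_duration_s[1],
                       artifact_params$shift_duration_s[2])
        for (try in 1:50) {
          st <- stats::runif(1, schedule$rest_end_s + 2,
                             schedule$task_end_s - dur - 2)
          if (nrow(occupied) == 0 ||
              all(st + dur < occupied[, 1] - 1 | st > occupied[, 2] + 1)) break
        }
        occupied <- rbind(occupied, c(st, st + dur))
        ch <- sample.int(nch, 1)
        i1 <- max(1L, round(st * fs) + 1L)
        i2 <- min(n, round((st + dur) * fs))
        shape <- if (kind == "spike")
          sin(pi * seq(0, 1, length.out = i2 - i1 + 1)) else
          rep(1, i2 - i1 + 1)
        k_sd <- if (kind == "spike") artifact_params$spike_k_sd else
          artifact_params$shift_k_sd
        for (w in seq_along(wl)) {
          amp <- k_sd * stats::sd(od[ch, , w])
          od[ch, i1:i2, w] <- od[ch, i1:i2, w] + amp * shape
        }
        artifact_log <- rbind(artifact_log,
                              data.frame(channel = ch, start_s = st,
                                         end_s = st + dur, kind = kind,
                                         stringsAsFactors = FALSE))
      }
    }

    intensity <- i0 * 10^(-od)
    rec <- optical_recording(intensity, stage = "intensity", fs_hz = fs,
                             wavelengths_nm = wl, montage = montage)
  }

  structure(
    list(id = id, group = group, hamd = as.integer(hamd),
         recording = rec, schedule = schedule, montage = montage,
         ground_truth = list(hbo = hbo_truth, hbo_with_nuisance = hbo_full,
                             hbr = hbr, regressor = reg,
                             artifact_log = artifact_log),
         seed = seed),
    class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s [%s, HAMD %d]\n", x$id, x$group, x$hamd))
  print(x$recording)
  invisible(x)
}

#' Simulate a two-group fNIRS cohort
#'
#' Generates `n_psd` depressed (PSD) and `n_nonpsd` non-depressed stroke
#' subjects under the oddball paradigm, each with their own seeded stimulus
#' schedule and recording. The group effect is planted in the inter-channel
#' covariance via [group_covariance_profiles()]; `effect_states` restricts
#' the plant to the rest and/or task state.
#'
#' @param n_psd,n_nonpsd Group sizes.
#' @param effect_size Planted effect scale (0 = null cohort).
#' @param effect_states States carrying the plant, subset of
#'   `c("rest", "task")`.
#' @param rest_duration_s Rest baseline length in seconds (20 by default;
#'   the rest block can be extended for better-conditioned rest-state
#'   connectivity).
#' @param task_duration_s Task block length in seconds.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @inheritParams generate_subject
#' @return An object of class `fnirs_cohort`: list of `subject_record`s plus
#'   a `manifest` data frame (id, group, hamd, seed).
#' @export
simulate_cohort <- function(n_psd = 19, n_nonpsd = 18,
                            effect_size = 1,
                            effect_states = c("rest", "task"),
                            rest_duration_s = 20, task_duration_s = 360,
                            noise_params = default_noise_params(),
                            artifact_params = default_artifact_params(),
                            hrf_params = default_hrf_params(),
                            output_stage = c("intensity", "hbo"),
                            seed = 1) {
  output_stage <- match.arg(output_stage)
  set.seed(seed)
  profiles <- group_covariance_profiles(
    effect_size = effect_size, effect_states = effect_states,
    sd_uM = if (noise_params$sd_uM > 0) noise_params$sd_uM else 0.5)
  montage <- dlpfc_montage()
  groups <- c(rep("PSD", n_psd), rep("nonPSD", n_nonpsd))
  ids <- sprintf("sub%02d", seq_along(groups))
  sub_seeds <- sample.int(.Machine$integer.max - 1, length(groups))

  subjects <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    sched <- generate_stimulus_schedule(task_duration_s = task_duration_s,
                                        rest_duration_s = rest_duration_s,
                                        seed = sub_seeds[k])
    subjects[[k]] <- generate_subject(
      id = ids[k], group = groups[k],
      state_covariances = profiles[[groups[k]]],
      schedule = sched, montage = montage,
      noise_params = noise_params, artifact_params = artifact_params,
      hrf_params = hrf_params, seed = sub_seeds[k],
      output_stage = output_stage)
  }
  manifest <- data.frame(
    id = ids, group = groups,
    hamd = vapply(subjects, function(s) s$hamd, integer(1)),
    seed = sub_seeds, stringsAsFactors = FALSE)
  structure(list(subjects = subjects, manifest = manifest,
                 effect_size = effect_size, effect_states = effect_states,
                 seed = seed),
            class = "fnirs_cohort")
}

#' @export
print.fnirs_cohort <- function(x, ...) {
  tb <- table(x$manifest$group)
  cat(sprintf("fNIRS cohort: %d subjects (%s), effect size %g in state(s) %s\n",
              nrow(x$manifest),
              paste(names(tb), tb, sep = "=", collapse = ", "),
              x$effect_size, paste(x$effect_states, collapse = "+")))
  invisible(x)
}
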