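# small od/intensity fixtures built in code
flat_intensity <- function(value = 500, nch = 2, n = 400, nwl = 3) {
  optical_recording(array(value, dim = c(nch, n, nwl)), stage = "intensity")
}

od_rec <- function(x, fs = 11) {
  # single-channel, single-wavelength od recording from a vector
  optical_recording(array(x, dim = c(1, length(x), 1)), stage = "od",
                    fs_hz = fs, wavelengths_nm = 850)
}

test_that("optical density conversion follows -log10(I/I0)", {
  # constant intensity: I = I0 everywhere, OD identically 0
  od <- intensity_to_od(flat_intensity())
  expect_equal(max(abs(od$data)), 0)

  # one sample at I0/10 must give OD close to 1 there (I0 barely moves)
  rec <- flat_intensity(n = 10000)
  rec$data[1, 5000, 1] <- 50
  od <- intensity_to_od(rec)
  expect_equal(od$data[1, 5000, 1], 1, tolerance = 1e-3)

  # exact identity against the analytic form
  set.seed(1)
  x <- array(exp(rnorm(2 * 100 * 3, log(500), 0.05)), dim = c(2, 100, 3))
  rec <- optical_recording(x, stage = "intensity")
  od <- intensity_to_od(rec)
  for (w in 1:3) {
    i0 <- rowMeans(x[, , w])
    expect_equal(od$data[, , w], -log10(x[, , w] / i0), tolerance = 1e-12)
  }

  # round trip through the inverse map
  i0 <- rowMeans(x[, , 1])
  back <- i0 * 10^(-od$data[, , 1])
  expect_equal(back, x[, , 1], tolerance = 1e-12)

  rec$data[2, 3, 1] <- -1
  expect_error(intensity_to_od(rec), "channel 2, sample 3")
})

test_that("motion-artifact detection implements the windowed 6-SD range rule", {
  fs <- 11
  t <- (0:999) / fs
  # slow smooth sinusoid: per-window range is far below 6 x trial SD
  x <- sin(2 * pi * 0.03 * t)
  m <- detect_motion_artifacts(od_rec(x))
  expect_identical(sum(m$flags), 0L)

  # a 10x-trial-SD step confined to one window flags exactly that window
  x2 <- x
  w <- round(0.5 * fs)
  win_id <- 40L
  idx <- ((win_id - 1) * w + 2):((win_id - 1) * w + 4)
  x2[idx] <- x2[idx] + 10 * sd(x)
  m2 <- detect_motion_artifacts(od_rec(x2))
  hit <- which(m2$flags[1, ])
  expect_identical(hit, win_id)
  seg <- x2[m2$windows[win_id, 1]:m2$windows[win_id, 2]]
  expect_gt(max(seg) - min(seg), 6 * sd(x2))
})

test_that("flag decisions equal an exhaustive per-window oracle", {
  fs <- 11
  set.seed(42)
  for (rep in 1:100) {
    x <- cumsum(rnorm(300)) / 10
    if (rep %% 3 == 0) x[sample(250, 1) + 0:3] <- x[100] + runif(1, 5, 12)
    m <- detect_motion_artifacts(od_rec(x), window_s = 0.5, k_sd = 6)
    thr <- 6 * sd(x)
    for (b in seq_len(nrow(m$windows))) {
      seg <- x[m$windows[b, 1]:m$windows[b, 2]]
      expect_identical(unname(m$flags[1, b]), (max(seg) - min(seg)) > thr)
    }
  }
})

test_that("spline correction removes spikes and leaves clean samples untouched", {
  fs <- 11
  t <- (0:999) / fs
  clean <- 0.01 * (t - 45)^3 / 1000 + 0.05 * sin(2 * pi * 0.02 * t)
  rec <- od_rec(clean)

  # empty mask: strict no-op
  m0 <- detect_motion_artifacts(rec)
  expect_identical(sum(m0$flags), 0L)
  expect_identical(correct_motion_artifacts(rec, m0)$data, rec$data)

  # spike in one window
  x <- clean
  spike_amp <- 10 * sd(clean)
  idx <- 445:449
  x[idx] <- x[idx] + spike_amp * sin(pi * seq(0, 1, length.out = 5))
  rec2 <- od_rec(x)
  m <- detect_motion_artifacts(rec2)
  expect_gt(sum(m$flags), 0)
  fixed <- correct_motion_artifacts(rec2, m)

  bad <- fnirsnet:::flagged_samples(m, 1)
  good <- setdiff(seq_along(x), bad)
  # unflagged samples unchanged bit-for-bit
  expect_identical(fixed$data[1, good, 1], x[good])
  # reconstruction error well under the spike amplitude
  rmse <- sqrt(mean((fixed$data[1, bad, 1] - clean[bad])^2))
  expect_lt(rmse, 0.05 * spike_amp)
  # contiguity at the window borders
  inc <- max(abs(diff(clean)))
  jumps <- abs(diff(fixed$data[1, , 1]))
  expect_lt(max(jumps), 10 * inc)
})

test_that("correction errors on fully flagged channels and fills edges by nearest value", {
  x <- rnorm(100)
  rec <- od_rec(x)
  m <- detect_motion_artifacts(rec)
  m$flags[1, ] <- TRUE
  expect_error(correct_motion_artifacts(rec, m), "entirely flagged")

  m$flags[1, ] <- FALSE
  m$flags[1, 1] <- TRUE  # recording edge: nearest-value extrapolation
  fixed <- correct_motion_artifacts(rec, m)
  first_good <- m$windows[1, 2] + 1
  expect_true(all(fixed$data[1, m$windows[1, 1]:m$windows[1, 2], 1] ==
                    x[first_good]))
  expect_match(attr(fixed, "edge_extrapolated"), "nearest clean value")
})

test_that("the zero-phase band-pass has the specified frequency response", {
  fs <- 11
  n <- 4400
  t <- (0:(n - 1)) / fs
  amp_at <- function(x, f) {
    sp <- Mod(fft(x))[1:(n / 2)]
    fr <- (0:(n / 2 - 1)) * fs / n
    sp[which.min(abs(fr - f))]
  }
  run <- function(x) {
    rec <- optical_recording(matrix(x, 1), stage = "hbo", fs_hz = fs)
    bandpass(rec)$data[1, ]
  }

  # DC is annihilated
  y <- run(rep(3, n))
  expect_lt(max(abs(y)), 3 * 1e-6)

  # 0.05 Hz passband tone preserved within 10%
  x1 <- sin(2 * pi * 0.05 * t)
  expect_equal(amp_at(run(x1), 0.05) / amp_at(x1, 0.05), 1, tolerance = 0.1)

  # 1.2 Hz cardiac tone attenuated by >= 20 dB (factor 10)
  x2 <- sin(2 * pi * 1.2 * t)
  expect_lt(amp_at(run(x2), 1.2) / amp_at(x2, 1.2), 0.1)

  # short recordings are rejected with advice
  short <- optical_recording(matrix(rnorm(220), 1), stage = "hbo", fs_hz = fs)
  expect_error(bandpass(short), "longer segment")
  expect_error(bandpass(optical_recording(matrix(rnorm(4400), 1),
                                          stage = "hbo", fs_hz = fs),
                        low_hz = 0.3, high_hz = 0.2), "band edges")
})

test_that("Beer-Lambert inversion is exact on forward-modeled optics", {
  set.seed(5)
  hbo <- matrix(rnorm(3 * 200, 0, 0.5), 3)
  hbr <- matrix(rnorm(3 * 200, 0, 0.2), 3)

  # zero OD maps to zero concentrations
  zero <- hemo_to_od(matrix(0, 2, 50), matrix(0, 2, 50))
  out0 <- od_to_hemo(zero)
  expect_equal(max(abs(out0$data)), 0)
  expect_equal(max(abs(out0$hbr)), 0)

  # forward then inverse recovers to 1e-9 relative error
  od <- hemo_to_od(hbo, hbr)
  rec <- od_to_hemo(od)
  expect_equal(rec$data, hbo, tolerance = 1e-9)
  expect_equal(rec$hbr, hbr, tolerance = 1e-9)

  # the 3-wavelength solve equals an explicit normal-equations oracle
  ext <- extinction_coefficients()
  A <- cbind(ext$eps_hbo, ext$eps_hbr) * 1e-6 * 3 * 6
  for (k in 1:20) {
    odv <- rnorm(3, 0, 0.02)
    ours <- od_to_hemo(optical_recording(array(odv, c(1, 1, 3)),
                                         stage = "od"))
    oracle <- solve(t(A) %*% A) %*% t(A) %*% odv
    expect_equal(c(ours$data[1, 1], ours$hbr[1, 1]), c(oracle),
                 tolerance = 1e-10)
  }

  bad <- optical_recording(array(rnorm(60), c(1, 10, 2)), stage = "od",
                           wavelengths_nm = c(850, 850))
  expect_error(od_to_hemo(bad), "duplicate")
})

test_that("the preprocessing driver applies the stages in the fixed order", {
  sched <- generate_stimulus_schedule(seed = 3)
  prof <- group_covariance_profiles(effect_size = 0)
  sub <- generate_subject("s", "PSD", prof$PSD, schedule = sched, seed = 8)
  res <- preprocess_recording(sub$recording)
  expect_identical(res$steps,
                   c("intensity_to_od", "detect_motion_artifacts",
                     "correct_motion_artifacts", "bandpass", "od_to_hemo"))
  expect_identical(res$recording$stage, "hbo")
})

test_that("artifact-free synthetic subjects are recovered within the passband", {
  sched <- generate_stimulus_schedule(seed = 10)
  prof <- group_covariance_profiles(effect_size = 1)
  sub <- generate_subject("s", "PSD", prof$PSD, schedule = sched,
                          artifact_params = no_artifact_params(), seed = 10)
  res <- preprocess_recording(sub$recording)
  truth <- sub$ground_truth$hbo
  for (ch in seq_len(nrow(truth))) {
    tb <- fnirsnet:::zerophase_bandpass(truth[ch, ], 11, 0.01, 0.2)
    expect_gte(cor(res$recording$data[ch, ], tb), 0.95)
    # residual below the injected nuisance floor
    nuis <- sub$ground_truth$hbo_with_nuisance[ch, ] - truth[ch, ]
    expect_lt(sd(res$recording$data[ch, ] - tb), sd(nuis))
  }
})

test_that("artifact correction is idempotent on already-clean data", {
  sched <- generate_stimulus_schedule(seed = 11)
  prof <- group_covariance_profiles(effect_size = 0)
  sub <- generate_subject("s", "PSD", prof$PSD, schedule = sched,
                          artifact_params = no_artifact_params(), seed = 11)
  od <- intensity_to_od(sub$recording)
  m1 <- detect_motion_artifacts(od)
  fixed <- correct_motion_artifacts(od, m1)
  m2 <- detect_motion_artifacts(fixed)
  fixed2 <- correct_motion_artifacts(fixed, m2)
  expect_lte(sum(m2$flags), sum(m1$flags))
  changed <- sum(fixed2$data != fixed$data)
  expect_identical(changed, 0L)
})
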