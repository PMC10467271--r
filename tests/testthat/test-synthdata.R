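test_that("stimulus schedules satisfy the oddball design invariants", {
  for (seed in 1:5) {
    s <- generate_stimulus_schedule(360, 20, 0.25, c(1, 3), seed = seed)
    expect_true(validate_stimulus_schedule(s))
    n <- length(s$onsets_s)
    expect_equal(sum(s$labels == "deviant"), round(0.25 * n))
    gaps <- diff(s$onsets_s)
    expect_true(all(gaps >= 1.05 - 1e-9 & gaps <= 3.05 + 1e-9))
    # mean gap ~ 2.05 s, so the count tracks 360 / mean-gap
    expect_equal(n, 360 / mean(gaps), tolerance = 0.05)
    expect_true(all(s$onsets_s >= 20 & s$onsets_s <= 380))
  }
})

test_that("deviant fraction 0 yields an all-standard train and short tasks error", {
  s <- generate_stimulus_schedule(deviant_fraction = 0, seed = 2)
  expect_true(all(s$labels == "standard"))
  expect_error(generate_stimulus_schedule(task_duration_s = 0.01),
               "too short")
})

test_that("the DLPFC montage has the fixed probe geometry", {
  m <- dlpfc_montage()
  expect_identical(nrow(m$sources), 7L)
  expect_identical(nrow(m$detectors), 6L)
  expect_identical(nrow(m$channels), 14L)
  expect_true(validate_montage(m))
})

test_that("group covariances are PSD, null at effect 0, and planted at effect 1", {
  # identical profiles under the null
  a <- generate_group_covariance("PSD", "task", effect_size = 0)
  b <- generate_group_covariance("nonPSD", "task", effect_size = 0)
  attributes(a) <- attributes(b) <- list(dim = dim(a))
  expect_identical(a, b)

  # task-state plant: mid-frontal to lateral coupling reduced in PSD
  p <- generate_group_covariance("PSD", "task", effect_size = 1)
  n <- generate_group_covariance("nonPSD", "task", effect_size = 1)
  for (j in c(1, 3, 4, 10, 11, 13, 14)) expect_lt(p[7, j], n[7, j])

  # rest-state plant: (4,6) and (2,5) elevated in PSD
  pr <- generate_group_covariance("PSD", "rest", effect_size = 1)
  nr <- generate_group_covariance("nonPSD", "rest", effect_size = 1)
  expect_gt(pr[4, 6], nr[4, 6])
  expect_gt(pr[2, 5], nr[2, 5])

  # PSD-ness under random strong plants (eigendecomposition oracle)
  set.seed(7)
  for (es in c(0.5, 1, 1.5, 2)) {
    cv <- suppressWarnings(generate_group_covariance("PSD", "task", es))
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_identical(cv, t(cv))
  }
})

test_that("nearest_psd clips negative eigenvalues and keeps symmetry", {
  set.seed(3)
  x <- matrix(rnorm(36), 6)
  x <- (x + t(x)) / 2
  y <- nearest_psd(x)
  expect_gte(min(eigen(y, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_identical(y, t(y))
})

test_that("with noise and artifacts disabled the HbO equals the evoked regressor", {
  sched <- generate_stimulus_schedule(seed = 4)
  prof <- group_covariance_profiles(effect_size = 0)
  sub <- generate_subject("s1", "PSD", prof$PSD, schedule = sched,
                          noise_params = no_noise_params(),
                          artifact_params = no_artifact_params(),
                          seed = 4, output_stage = "hbo")
  reg <- sub$ground_truth$regressor
  loadings <- fnirsnet:::channel_loadings(14)
  for (ch in c(1, 7, 14))
    expect_equal(sub$recording$data[ch, ], loadings[ch] * reg,
                 tolerance = 1e-12)
  # deviants evoke larger responses than standards by construction
  expect_gt(default_hrf_params()$amp_deviant_uM,
            default_hrf_params()$amp_standard_uM)
})

test_that("subjects are bitwise reproducible from their seed", {
  sched <- generate_stimulus_schedule(seed = 9)
  prof <- group_covariance_profiles(effect_size = 1)
  s1 <- generate_subject("a", "PSD", prof$PSD, schedule = sched, seed = 11)
  s2 <- generate_subject("a", "PSD", prof$PSD, schedule = sched, seed = 11)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$hamd, s2$hamd)
  expect_identical(s1$ground_truth$artifact_log, s2$ground_truth$artifact_log)
})

test_that("HAMD scores respect the diagnostic cut and groups label correctly", {
  sched <- generate_stimulus_schedule(seed = 5)
  prof <- group_covariance_profiles(effect_size = 0)
  for (k in 1:5) {
    sp <- generate_subject("p", "PSD", prof$PSD, schedule = sched,
                           seed = k, output_stage = "hbo",
                           noise_params = quiet_noise(),
                           artifact_params = no_artifact_params())
    sn <- generate_subject("n", "nonPSD", prof$nonPSD, schedule = sched,
                           seed = k + 100, output_stage = "hbo",
                           noise_params = quiet_noise(),
                           artifact_params = no_artifact_params())
    expect_gte(sp$hamd, 8)
    expect_lt(sn$hamd, 8)
  }
  expect_error(generate_subject("p", "PSD", prof$PSD, schedule = sched,
                                seed = 1, hamd = 3, output_stage = "hbo"),
               "HAMD")
})

test_that("injected spikes are logged and exceed 6x the trial SD in OD space", {
  sched <- generate_stimulus_schedule(seed = 6)
  prof <- group_covariance_profiles(effect_size = 0)
  ap <- no_artifact_params()
  ap$n_spikes <- 1
  sub <- generate_subject("s", "PSD", prof$PSD, schedule = sched,
                          artifact_params = ap, seed = 12)
  log <- sub$ground_truth$artifact_log
  expect_identical(nrow(log), 1L)
  expect_identical(log$kind, "spike")
  expect_true(log$start_s >= 0 && log$end_s <= sched$task_end_s)

  od <- intensity_to_od(sub$recording)
  ch <- log$channel
  fs <- sub$recording$fs_hz
  idx <- (round(log$start_s * fs) + 1):round(log$end_s * fs)
  x <- od$data[ch, , 1]
  expect_gt(max(x[idx]) - min(x), 6 * sd(x))
})

test_that("noise-only sample correlations converge to the planted values", {
  # Monte-Carlo over 50 seeds on the 3960-sample task segment
  prof <- group_covariance_profiles(effect_size = 1)
  target <- attr(prof$PSD$task, "correlation")
  np <- quiet_noise()
  hrf0 <- default_hrf_params()
  hrf0$amp_deviant_uM <- 0; hrf0$amp_standard_uM <- 0  # noise only
  pairs <- rbind(c(7, 1), c(2, 3), c(1, 14))
  acc <- matrix(0, 50, nrow(pairs))
  sched <- generate_stimulus_schedule(seed = 1)
  for (k in 1:50) {
    sub <- generate_subject("s", "PSD", prof$PSD, schedule = sched,
                            noise_params = np, hrf_params = hrf0,
                            artifact_params = no_artifact_params(),
                            seed = 1000 + k, output_stage = "hbo")
    seg <- segment_states(sub$recording, sub$schedule)
    r <- cor(t(seg$task))
    acc[k, ] <- r[pairs]
  }
  for (q in seq_len(nrow(pairs)))
    expect_equal(mean(acc[, q]), target[pairs[q, 1], pairs[q, 2]],
                 tolerance = 0.05)
})

test_that("cohorts are deterministic in their master seed", {
  c1 <- hbo_cohort(3, 3, 1, "task", seed = 21)
  c2 <- hbo_cohort(3, 3, 1, "task", seed = 21)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$subjects[[5]]$recording$data,
                   c2$subjects[[5]]$recording$data)
})
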