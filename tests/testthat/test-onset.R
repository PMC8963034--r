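test_that("TKEO matches its definition", {
  expect_equal(tkeo(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(tkeo(c(0, 1, 0)), c(0, 1, 0))

  set.seed(4)
  x <- rnorm(100)
  brute <- numeric(100)
  for (i in 2:99) brute[i] <- x[i]^2 - x[i + 1] * x[i - 1]
  expect_lt(max(abs(tkeo(x) - brute)), 1e-12)

  expect_error(tkeo(c(1, 2)), "at least 3")
})

test_that("channel conditioning is nonnegative and the stage order matters", {
  expect_equal(condition_channels(matrix(0, 8, 400)), matrix(0, 8, 400))

  set.seed(5)
  emg <- matrix(rnorm(8 * 400), 8)
  psi <- condition_channels(emg)
  expect_true(all(psi >= 0))

  # swapping rectification before the low-pass is a different pipeline
  lp <- butter_design(4, 50, 200, "lowpass")
  swapped <- t(apply(emg, 1, function(ch) filtfilt(lp, abs(tkeo(ch)))))
  expect_gt(max(abs(psi - swapped)), 1e-3)
})

test_that("channel averaging and RMS smoothing match brute force", {
  m <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(average_channels(m), c(1, 1))
  one <- matrix(rep(1:5, each = 8), 8)
  expect_equal(average_channels(one), 1:5 + 0)

  set.seed(6)
  psi <- abs(matrix(rnorm(8 * 50), 8))
  expect_lt(max(abs(average_channels(psi) - apply(psi, 2, function(col) sum(col) / 8))), 1e-12)

  x <- abs(rnorm(200))
  expect_equal(rms_smooth(rep(3, 100), 60), rep(3, 41))
  expect_equal(rms_smooth(x, 1), x)
  W <- 60
  brute <- vapply(seq_len(200 - W + 1), function(i) sqrt(mean(x[i:(i + W - 1)]^2)), 0)
  expect_lt(max(abs(rms_smooth(x, W) - brute)), 1e-12)
  expect_identical(length(rms_smooth(x, W)), 200L - 60L + 1L)
  expect_error(rms_smooth(x[1:10], 60), "shorter")
})

test_that("double-threshold detection finds a clean burst and flags multi-burst trials", {
  env <- burst_envelope(600, 300, 40)
  seg <- detect_active_region(env)
  expect_identical(seg$status, "auto")
  expect_lte(seg$onset_idx, 300)
  expect_gte(seg$offset_idx, 300)
  expect_equal(seg$offset_threshold / seg$onset_threshold, 0.6)

  # independent threshold oracle on the constructed burst
  peaks <- which(diff(sign(diff(env))) == -2) + 1
  peaks <- peaks[env[peaks] > 0.1 * max(env)]
  thr <- 0.2 * mean(env[peaks])
  expect_equal(seg$onset_threshold, thr)
  expect_identical(seg$onset_idx, which(env >= thr)[1])
  expect_identical(seg$offset_idx, max(which(env >= 0.6 * thr)))

  two <- burst_envelope(900, 250, 30) + burst_envelope(900, 650, 30)
  seg2 <- detect_active_region(two)
  expect_identical(seg2$status, "ambiguous")
  expect_identical(nrow(seg2$candidates), 2L)

  expect_error(detect_active_region(rep(0, 100)), "no activity")
})

test_that("detection indices are invariant to amplitude scaling and sign flips", {
  rec <- preprocess_recording(fixture_trial())
  psi <- condition_channels(rec$emg)
  env <- rms_smooth(average_channels(psi), 60)
  seg <- detect_active_region(env)

  seg5 <- detect_active_region(rms_smooth(average_channels(condition_channels(5 * rec$emg)), 60))
  expect_identical(seg5$onset_idx, seg$onset_idx)
  expect_identical(seg5$offset_idx, seg$offset_idx)
  expect_equal(seg5$onset_threshold, 25 * seg$onset_threshold)

  envf <- rms_smooth(average_channels(condition_channels(-rec$emg)), 60)
  expect_lt(max(abs(envf - env)), 1e-9 * max(env))
})

test_that("apply_segment trims both modalities consistently", {
  emg <- matrix(rnorm(8 * 100), 8)
  imu <- matrix(rnorm(6 * 100), 6)
  full <- apply_segment(list(onset_idx = 1, offset_idx = 100), emg, imu)
  expect_identical(full$emg, emg)

  seg <- apply_segment(list(onset_idx = 11, offset_idx = 60), emg, imu)
  expect_identical(ncol(seg$emg), 50L)
  expect_identical(ncol(seg$imu), 50L)

  expect_error(apply_segment(list(onset_idx = 0, offset_idx = 60), emg, imu), "bounds")
  expect_error(apply_segment(list(onset_idx = 50, offset_idx = 101), emg, imu), "bounds")
})

test_that("the detector hits planted onsets on a high-SNR cohort", {
  cfg <- small_cfg(n_subjects = 1, n_positions = 2, n_repetitions = 3,
                   emg_noise_sd = 0.01, seed = 77L)
  coh <- generate_cohort(cfg)
  err <- c()
  auto <- c()
  for (rec in coh$subjects[[1]]$recordings) {
    rec <- preprocess_recording(rec)
    seg <- detect_recording(rec)
    auto <- c(auto, seg$status == "auto")
    err <- c(err, seg$onset_idx - rec$true_onset)
  }
  expect_gte(mean(abs(err) <= 0.15 * 200), 0.95)
  expect_gte(mean(auto), 0.70)
})
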