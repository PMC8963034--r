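#' Synthetic multi-subject EMG + IMU cohorts
#'
#' The study data behind this pipeline are not public, so the package ships
#' a seeded generator that emulates the recording protocol: seven hand
#' gestures held for five seconds with three seconds of rest on either
#' side, ten repetitions in each of four arm positions, eight EMG channels
#' at 200 Hz and a six-axis IMU at 50 Hz. The EMG model is the standard
#' surface-EMG surrogate -- an amplitude-modulated, band-limited (20-95 Hz)
#' Gaussian carrier -- plus baseline noise, a DC offset and 60 Hz power-line
#' interference, so the preprocessing filters have something to remove.
#' Subject individuality enters as per-channel gain jitter and a circular
#' rotation of the electrode ring (armband donning variability); arm
#' position enters as the gravity direction seen by the accelerometer.
#' Ground-truth onset/offset indices are stored with every trial.
#'
#' @name synthetic_data
NULL

#' Cohort configuration
#'
#' Protocol constants default to the recording protocol the pipeline
#' assumes; the active (gesture-motion) region is 4.8 s of the 5 s hold,
#' which yields exactly 37 overlapping 250 ms / 50% windows.
#'
#' @param n_subjects number of subjects.
#' @param n_gestures number of gesture classes (default 7).
#' @param n_positions number of arm positions (default 4).
#' @param n_repetitions repetitions per gesture and position (default 10).
#' @param hold_s gesture hold duration, seconds.
#' @param rest_s rest before and after the hold, seconds.
#' @param emg_rate,imu_rate sampling rates, Hz; `emg_rate` must be an
#'   integer multiple of `imu_rate`.
#' @param emg_noise_sd baseline EMG noise sd in arbitrary units (active
#'   channel amplitudes are roughly 0.25-1). Lower it for a high-SNR
#'   cohort.
#' @param powerline_amp amplitude of the 60 Hz interference.
#' @param separability in `[0, 1]`: 1 keeps the gesture activation
#'   templates and gesture-specific IMU motion fully distinct; 0 collapses
#'   all gestures onto their common mean, so classes are statistically
#'   identical.
#' @param seed root seed; every trial derives its own stream from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 22, n_gestures = 7, n_positions = 4,
                          n_repetitions = 10, hold_s = 5, rest_s = 3,
                          emg_rate = 200, imu_rate = 50,
                          emg_noise_sd = 0.05, powerline_amp = 0.1,
                          separability = 1, seed = 1L) {
  counts <- c(n_subjects, n_gestures, n_positions, n_repetitions)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  if (emg_rate %% imu_rate != 0)
    stop("emg_rate must be an integer multiple of imu_rate")
  if (separability < 0 || separability > 1)
    stop("separability must lie in [0, 1]")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_gestures = as.integer(n_gestures),
                 n_positions = as.integer(n_positions),
                 n_repetitions = as.integer(n_repetitions),
                 hold_s = hold_s, rest_s = rest_s,
                 emg_rate = emg_rate, imu_rate = imu_rate,
                 emg_noise_sd = emg_noise_sd, powerline_amp = powerline_amp,
                 separability = separability, seed = as.integer(seed)),
            class = "cohort_config")
}

# canonical gesture -> channel activation templates (n_gestures x 8).
# Gesture g activates a bump of muscles centred on channel g with a
# smaller secondary bump, so templates are pairwise distinct.
base_templates <- function(n_gestures = 7, n_channels = 8, separability = 1) {
  tpl <- matrix(0, n_gestures, n_channels)
  for (g in seq_len(n_gestures)) {
    d1 <- pmin(abs(seq_len(n_channels) - g), n_channels - abs(seq_len(n_channels) - g))
    d2 <- pmin(abs(seq_len(n_channels) - (g + 3)), n_channels - abs(seq_len(n_channels) - (g + 3)))
    tpl[g, ] <- 0.2 + 0.9 * exp(-0.5 * (d1 / 0.9)^2) + 0.35 * exp(-0.5 * (d2 / 0.9)^2)
  }
  ctr <- matrix(colMeans(tpl), n_gestures, n_channels, byrow = TRUE)
  ctr + separability * (tpl - ctr)
}

# gravity direction (unit vector, g units) per arm position
position_gravity <- function(position_id) {
  dirs <- rbind(c(0, 0, 1),
                c(0, sin(pi / 4), cos(pi / 4)),
                c(0, sin(5 * pi / 12), cos(5 * pi / 12)),
                c(sin(pi / 6), sin(pi / 4) * cos(pi / 6), cos(pi / 4) * cos(pi / 6)))
  i <- ((position_id - 1) %% 4) + 1
  dirs[i, ] / sqrt(sum(dirs[i, ]^2))
}

# gesture-specific IMU motion directions (accelerometer and gyroscope)
gesture_motion_dirs <- function(n_gestures = 7) {
  ang <- 2 * pi * (seq_len(n_gestures) - 1) / n_gestures
  acc <- cbind(cos(ang), sin(ang), sin(2 * ang) * 0.5)
  gyr <- cbind(sin(ang), cos(2 * ang), cos(ang) * 0.6)
  list(acc = acc / sqrt(rowSums(acc^2)), gyr = gyr / sqrt(rowSums(gyr^2)))
}

#' Draw a subject profile
#'
#' Per-subject latent factors: positive channel gains (log-normal jitter),
#' a circular rotation of the electrode ring in `{0..7}`, the subject's
#' gesture activation templates, and a latent style vector used only by
#' planted-model fixtures.
#'
#' @param cfg a [cohort_config()].
#' @param subject_id integer id.
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(cfg, subject_id) {
  with_seed(derive_seed(cfg$seed, 101L, subject_id), {
    gains <- exp(rnorm(8, 0, 0.3))
    # donning variability: the protocol anchors sensor 4 on a landmark, so
    # most subjects sit at rotation 0 with occasional one-channel shifts
    rotation <- sample(c(0L, 1L, 7L), 1, prob = c(0.5, 0.25, 0.25))
    tpl <- base_templates(cfg$n_gestures, 8, cfg$separability)
    # subject-specific activation deviations: a per-channel part shared by
    # all gestures plus a gesture-specific part that vanishes when the
    # gesture templates are collapsed (separability = 0)
    ch_jit <- rnorm(8, 0, 0.1)
    tpl <- tpl * exp(matrix(ch_jit, nrow(tpl), 8, byrow = TRUE) +
                       cfg$separability * matrix(rnorm(length(tpl), 0, 0.18), nrow(tpl)))
    style <- rnorm(2)
    structure(list(subject_id = as.integer(subject_id),
                   channel_gains = gains,
                   channel_rotation = as.integer(rotation),
                   activation_templates = tpl,
                   style_vector = style),
              class = "subject_profile")
  })
}

# smooth activation envelope on the 200 Hz grid: raised-cosine ramps of
# `ramp` samples at both ends of the active span [onset, offset]
activation_envelope <- function(n, onset, offset, ramp = 40) {
  env <- numeric(n)
  span <- onset:offset
  env[span] <- 1
  up <- seq_len(ramp)
  env[onset + up - 1] <- 0.5 * (1 - cos(pi * up / ramp))
  env[offset - ramp + up] <- 0.5 * (1 + cos(pi * up / ramp))
  env
}

generate_trial <- function(profile, cfg, gesture_id, position_id, repetition) {
  n_e <- round((2 * cfg$rest_s + cfg$hold_s) * cfg$emg_rate)
  n_i <- round((2 * cfg$rest_s + cfg$hold_s) * cfg$imu_rate)
  ratio <- cfg$emg_rate / cfg$imu_rate
  # active span: 4.8 s of the 5 s hold => 37 windows at 250 ms / 50%
  active_len <- round(0.96 * cfg$hold_s * cfg$emg_rate)
  true_onset <- round(cfg$rest_s * cfg$emg_rate) + round(0.02 * cfg$hold_s * cfg$emg_rate)
  true_offset <- true_onset + active_len - 1

  with_seed(derive_seed(cfg$seed, profile$subject_id, gesture_id, position_id, repetition), {
    env <- activation_envelope(n_e, true_onset, true_offset,
                               ramp = max(8L, round(0.08 * cfg$hold_s * cfg$emg_rate)))
    # channel amplitudes: gesture template, electrode ring rotated per subject
    tpl <- profile$activation_templates[gesture_id, ]
    rot <- profile$channel_rotation
    tpl <- tpl[((seq_len(8) - 1 + rot) %% 8) + 1]
    amp <- tpl * profile$channel_gains

    # gesture-specific carrier band: different muscle groups differ mildly
    # in spectral content, which makes ZC/AR features class-informative
    hi_edge <- min(95, 0.475 * cfg$emg_rate) - 4 * cfg$separability * (gesture_id - 1)
    carrier_filt <- butter_design(4, c(20, hi_edge), cfg$emg_rate, "bandpass")
    t_e <- (seq_len(n_e) - 1) / cfg$emg_rate
    dc <- with_seed(derive_seed(cfg$seed, 202L, profile$subject_id), rnorm(8, 0.4, 0.1))
    emg <- matrix(0, 8, n_e)
    for (ch in seq_len(8)) {
      carrier <- filtfilt(carrier_filt, rnorm(n_e))
      carrier <- carrier / stats::sd(carrier)
      emg[ch, ] <- amp[ch] * env * carrier +
        rnorm(n_e, 0, cfg$emg_noise_sd) + dc[ch] +
        cfg$powerline_amp * sin(2 * pi * 60 * t_e + ch)
    }

    # IMU: gravity per position + gesture-correlated motion + noise
    t_i <- (seq_len(n_i) - 1) / cfg$imu_rate
    env_i <- env[seq(1, by = ratio, length.out = n_i)]
    dirs <- gesture_motion_dirs(cfg$n_gestures)
    sep <- cfg$separability
    # oscillation fast enough that a 250 ms window sees >= 1.5 cycles, so
    # per-window amplitude features are phase-stable
    f_g <- 6 + 0.6 * sep * (gesture_id - 1)
    a_amp <- 0.12 + 0.04 * sep * (gesture_id - 1)
    g_amp <- 25 + 6 * sep * (gesture_id - 1)
    acc_dir <- dirs$acc[gesture_id, ] * sep + (1 - sep) * colMeans(dirs$acc)
    gyr_dir <- dirs$gyr[gesture_id, ] * sep + (1 - sep) * colMeans(dirs$gyr)
    grav <- position_gravity(position_id)
    osc_a <- env_i * sin(2 * pi * f_g * t_i)
    osc_g <- env_i * cos(2 * pi * f_g * t_i)
    accel <- t(outer(rep(1, n_i), grav)) +
      a_amp * acc_dir %o% osc_a +
      matrix(rnorm(3 * n_i, 0, 0.02), 3)
    gyro <- g_amp * gyr_dir %o% osc_g + matrix(rnorm(3 * n_i, 0, 0.8), 3)

    structure(list(emg = emg, accel = accel, gyro = gyro,
                   subject_id = profile$subject_id,
                   gesture_id = as.integer(gesture_id),
                   position_id = as.integer(position_id),
                   repetition = as.integer(repetition),
                   true_onset = as.integer(true_onset),
                   true_offset = as.integer(true_offset),
                   emg_rate = cfg$emg_rate, imu_rate = cfg$imu_rate),
              class = "raw_recording")
  })
}

#' Generate all recordings for one subject
#'
#' @param profile a [subject_profile()].
#' @param cfg a [cohort_config()].
#' @return list of `raw_recording` objects, ordered gesture-major, then
#'   position, then repetition; length
#'   `n_gestures * n_positions * n_repetitions`.
#' @export
generate_subject <- function(profile, cfg) {
  out <- vector("list", cfg$n_gestures * cfg$n_positions * cfg$n_repetitions)
  i <- 1L
  for (g in seq_len(cfg$n_gestures))
    for (p in seq_len(cfg$n_positions))
      for (r in seq_len(cfg$n_repetitions)) {
        out[[i]] <- generate_trial(profile, cfg, g, p, r)
        i <- i + 1L
      }
  out
}

#' Generate a cohort, optionally writing it to disk
#'
#' @param cfg a [cohort_config()].
#' @param out_dir if non-`NULL`, the cohort is also written as one CSV per
#'   sensor stream per trial plus a JSON metadata file per trial, under one
#'   directory per subject.
#' @return list with elements `cfg` and `subjects`; each subject is a list
#'   with `profile` and `recordings`.
#' @export
generate_cohort <- function(cfg, out_dir = NULL) {
  subjects <- lapply(seq_len(cfg$n_subjects), function(s) {
    profile <- subject_profile(cfg, s)
    list(profile = profile, recordings = generate_subject(profile, cfg))
  })
  cohort <- list(cfg = cfg, subjects = subjects)
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

trial_stem <- function(rec) {
  sprintf("trial_g%d_p%d_r%02d", rec$gesture_id, rec$position_id, rec$repetition)
}

#' Write / read the on-disk cohort layout
#'
#' One directory per subject; per trial an EMG CSV (`t, ch1..ch8`), an IMU
#' CSV (`t, ax, ay, az, gx, gy, gz`) and a JSON metadata file carrying the
#' labels, rates and ground-truth onset/offset.
#'
#' @param cohort as returned by [generate_cohort()].
#' @param dir output directory.
#' @return `write_cohort`: `dir`, invisibly. `read_cohort`: a cohort list
#'   (without profiles, which are generator-internal).
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  for (sub in cohort$subjects) {
    sdir <- file.path(dir, sprintf("subject_%02d", sub$profile$subject_id))
    dir.create(sdir, showWarnings = FALSE)
    for (rec in sub$recordings) {
      stem <- file.path(sdir, trial_stem(rec))
      n_e <- ncol(rec$emg); n_i <- ncol(rec$accel)
      emg_df <- data.frame(t = (seq_len(n_e) - 1) / rec$emg_rate, t(rec$emg))
      names(emg_df) <- c("t", paste0("ch", 1:8))
      imu_df <- data.frame(t = (seq_len(n_i) - 1) / rec$imu_rate,
                           t(rec$accel), t(rec$gyro))
      names(imu_df) <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
      write.csv(emg_df, paste0(stem, "_emg.csv"), row.names = FALSE)
      write.csv(imu_df, paste0(stem, "_imu.csv"), row.names = FALSE)
      meta <- list(subject = rec$subject_id, gesture = rec$gesture_id,
                   position = rec$position_id, repetition = rec$repetition,
                   emg_rate = rec$emg_rate, imu_rate = rec$imu_rate,
                   true_onset = rec$true_onset, true_offset = rec$true_offset)
      jsonlite::write_json(meta, paste0(stem, "_meta.json"), auto_unbox = TRUE)
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  sdirs <- sort(list.dirs(dir, recursive = FALSE))
  subjects <- lapply(sdirs, function(sdir) {
    metas <- sort(list.files(sdir, pattern = "_meta\\.json$", full.names = TRUE))
    recordings <- lapply(metas, function(mf) {
      meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
      stem <- sub("_meta\\.json$", "", mf)
      emg_df <- read.csv(paste0(stem, "_emg.csv"))
      imu_df <- read.csv(paste0(stem, "_imu.csv"))
      structure(list(emg = t(as.matrix(emg_df[, -1])),
                     accel = t(as.matrix(imu_df[, 2:4])),
                     gyro = t(as.matrix(imu_df[, 5:7])),
                     subject_id = meta$subject, gesture_id = meta$gesture,
                     position_id = meta$position, repetition = meta$repetition,
                     true_onset = meta$true_onset, true_offset = meta$true_offset,
                     emg_rate = meta$emg_rate, imu_rate = meta$imu_rate),
                class = "raw_recording")
    })
    # order to match the generator: gesture-major, then position, then rep
    ord <- order(vapply(recordings, `[[`, 1L, "gesture_id"),
                 vapply(recordings, `[[`, 1L, "position_id"),
                 vapply(recordings, `[[`, 1L, "repetition"))
    recordings[ord]
  })
  list(subjects = lapply(subjects, function(r) list(profile = NULL, recordings = r)))
}

#' Plant an exact bilinear style/content dataset
#'
#' Draws ground-truth style vectors (one per subject), content vectors (one
#' per motion sample), and per-channel weight matrices, and returns noisy
#' observations `obs[t, k] = z[s(t)]' W_k x[t] + e`. Used as the oracle
#' fixture for the bilinear fitting module.
#'
#' Motion samples correspond across subjects (every subject performs the
#' same motions), so content vectors are shared: observation row
#' `(s, m)` is `z_s' W_k x_m` plus noise. This is the complete
#' style-by-content grid the factorization module assumes.
#'
#' @param n_subjects subjects (styles).
#' @param n_motions motion samples, shared across subjects.
#' @param I,J style and content dimensions.
#' @param noise_sd observation noise sd (>= 0).
#' @param seed RNG seed.
#' @param n_channels number of observation channels K.
#' @return list with `styles` (S x I), `contents` (n_motions x J, shared),
#'   `weights` (I x J x K array), `observations` ((S * n_motions) x K,
#'   subject-major), `subject_index` and `motion_index` (length
#'   S * n_motions).
#' @export
plant_bilinear_dataset <- function(n_subjects, n_motions, I = 2, J = 3,
                                   noise_sd = 0, seed = 1L, n_channels = 8) {
  stopifnot(I >= 1, J >= 1, noise_sd >= 0, n_subjects >= 1, n_motions >= 1)
  with_seed(derive_seed(seed, 303L), {
    S <- n_subjects; M <- n_motions; Tn <- S * M; K <- n_channels
    styles <- matrix(rnorm(S * I), S, I)
    contents <- matrix(rnorm(M * J), M, J)
    weights <- array(rnorm(I * J * K), c(I, J, K))
    subject_index <- rep(seq_len(S), each = M)
    motion_index <- rep(seq_len(M), S)
    obs <- matrix(0, Tn, K)
    for (k in seq_len(K)) {
      zw <- styles %*% weights[, , k]            # S x J
      obs[, k] <- rowSums(zw[subject_index, , drop = FALSE] *
                            contents[motion_index, , drop = FALSE])
    }
    if (noise_sd > 0) obs <- obs + matrix(rnorm(Tn * K, 0, noise_sd), Tn, K)
    list(styles = styles, contents = contents, weights = weights,
         observations = obs, subject_index = subject_index,
         motion_index = motion_index)
  })
}
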