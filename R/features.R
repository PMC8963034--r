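#' Time-domain feature extraction and feature-level fusion
#'
#' Active segments are cut into overlapping 250 ms windows with 50%
#' overlap (50 samples / step 25 at 200 Hz). Each EMG window yields, per
#' channel: mean absolute value (MAV), MAV slope (MAVS, the difference to
#' the previous window of the same segment; 0 for the first window),
#' waveform length (WL), four Burg autoregressive coefficients (AR1-AR4,
#' prediction convention `x_i = sum_k a_k x_{i-k} + e`), and the
#' zero-crossing count (ZC, deadband 0 by default) -- 64 features over 8
#' channels. Each IMU window yields MAV and WL per axis -- 12 features.
#' Fusion concatenates the EMG block first, then the IMU block (76).
#'
#' @name features
NULL

#' Window start indices
#'
#' Windows start at 1, 1 + step, ...; only full windows are kept, so the
#' count is `floor((L - width) / step) + 1`.
#'
#' @param L segment length in samples.
#' @param width window length (default 50 samples = 250 ms at 200 Hz).
#' @param step hop size (default 25 = 50% overlap).
#' @return integer vector of start indices.
#' @export
window_starts <- function(L, width = 50, step = 25) {
  if (L < width) stop("segment shorter than one window")
  seq.int(1L, by = step, length.out = (L - width) %/% step + 1L)
}

#' Cut a segment into overlapping windows
#'
#' @param segment channels x L matrix.
#' @param width,step see [window_starts()].
#' @return list of channels x width matrices.
#' @export
window_segment <- function(segment, width = 50, step = 25) {
  starts <- window_starts(ncol(segment), width, step)
  lapply(starts, function(s) segment[, s:(s + width - 1), drop = FALSE])
}

# Burg AR coefficients, vectorized over the columns of X (samples x windows).
# Returns order x K matrix of prediction-form coefficients; columns where
# the recursion degenerates (zero energy) are set to 0.
burg_ar <- function(X, order = 4) {
  n <- nrow(X); K <- ncol(X)
  if (n <= order + 1) stop("window too short for AR order ", order)
  A <- matrix(0, order, K)
  F <- X; B <- X
  dead <- rep(FALSE, K)
  for (m in seq_len(order)) {
    r <- nrow(F)
    f <- F[2:r, , drop = FALSE]
    b <- B[1:(r - 1), , drop = FALSE]
    den <- colSums(f^2) + colSums(b^2)
    dead <- dead | den <= 0
    k <- ifelse(den > 0, 2 * colSums(f * b) / den, 0)
    if (m > 1) {
      prev <- A[1:(m - 1), , drop = FALSE]
      A[1:(m - 1), ] <- prev - rep(k, each = m - 1) * prev[(m - 1):1, , drop = FALSE]
    }
    A[m, ] <- k
    km <- rep(k, each = r - 1)
    F <- f - km * b
    B <- b - km * f
  }
  if (any(dead)) {
    A[, dead] <- 0
    warning("degenerate (constant) window: AR coefficients set to 0")
  }
  A
}

# zero crossings with deadband eps: sign change and jump size > eps
zero_crossings <- function(X, eps = 0) {
  n <- nrow(X)
  x1 <- X[1:(n - 1), , drop = FALSE]
  x2 <- X[2:n, , drop = FALSE]
  colSums(x1 * x2 < 0 & abs(x1 - x2) > eps)
}

#' Canonical feature names
#'
#' Per-channel EMG blocks `[MAV, MAVS, WL, AR1..AR4, ZC]` for channels
#' 1..8, then `[MAV, WL]` per IMU axis (ax, ay, az, gx, gy, gz). This
#' order is frozen across the package.
#'
#' @param modality `"emg"`, `"imu"` or `"fused"`.
#' @return character vector of length 64, 12 or 76.
#' @export
feature_names <- function(modality = c("fused", "emg", "imu")) {
  modality <- match.arg(modality)
  emg <- as.vector(vapply(1:8, function(ch)
    paste0("ch", ch, "_", c("MAV", "MAVS", "WL", "AR1", "AR2", "AR3", "AR4", "ZC")),
    character(8)))
  imu <- as.vector(vapply(c("ax", "ay", "az", "gx", "gy", "gz"),
                          function(ax) paste0(ax, "_", c("MAV", "WL")), character(2)))
  switch(modality, emg = emg, imu = imu, fused = c(emg, imu))
}

#' EMG features for one window
#'
#' @param window 8 x width matrix of filtered EMG.
#' @param prev_mav MAV of the previous window of the same segment (length
#'   8), or `NULL` for the first window (MAVS = 0).
#' @param zc_eps zero-crossing deadband.
#' @return length-64 named vector.
#' @export
emg_features <- function(window, prev_mav = NULL, zc_eps = 0) {
  X <- t(window)                       # samples x channels
  mav <- colMeans(abs(X))
  mavs <- if (is.null(prev_mav)) rep(0, ncol(X)) else mav - prev_mav
  wl <- colSums(abs(diff(X)))
  ar <- burg_ar(X, 4)
  zc <- zero_crossings(X, zc_eps)
  v <- as.vector(rbind(mav, mavs, wl, ar, zc))
  names(v) <- feature_names("emg")
  v
}

#' IMU features for one window
#'
#' @param window 6 x width matrix (filtered, upsampled IMU).
#' @return length-12 named vector (MAV and WL per axis).
#' @export
imu_features <- function(window) {
  X <- t(window)
  v <- as.vector(rbind(colMeans(abs(X)), colSums(abs(diff(X)))))
  names(v) <- feature_names("imu")
  v
}

#' Feature-level fusion
#'
#' @param emg_vec length-64 EMG feature vector.
#' @param imu_vec length-12 IMU feature vector (or length 0 for EMG-only).
#' @return concatenated vector, EMG block first.
#' @export
fuse <- function(emg_vec, imu_vec) {
  if (length(imu_vec) == 0) return(emg_vec)
  if (length(emg_vec) != 64 || length(imu_vec) != 12)
    stop("expected 64 EMG and 12 IMU features")
  c(emg_vec, imu_vec)
}

#' Featurize one active segment
#'
#' Windows the EMG and IMU segments jointly and returns the fused
#' windows x 76 matrix. MAVS is computed within the segment.
#'
#' @param emg_seg 8 x L matrix.
#' @param imu_seg 6 x L matrix on the same timeline.
#' @param width,step windowing parameters.
#' @param zc_eps zero-crossing deadband.
#' @param window_stride keep (and compute) every n-th window; MAVS is then
#'   the difference between consecutive kept windows.
#' @return n_windows x 76 matrix with column names [feature_names()]; the
#'   kept window indices are in `attr(, "window_ids")`.
#' @export
featurize_segment <- function(emg_seg, imu_seg, width = 50, step = 25, zc_eps = 0,
                              window_stride = 1L) {
  starts <- window_starts(ncol(emg_seg), width, step)
  keep <- seq(1L, length(starts), by = window_stride)
  starts <- starts[keep]
  nw <- length(starts)
  idx <- outer(seq_len(width) - 1L, starts, "+")     # width x nw index grid
  out <- matrix(0, nw, 76, dimnames = list(NULL, feature_names("fused")))
  for (ch in 1:8) {
    Xw <- matrix(emg_seg[ch, idx], width)            # windows as columns
    mav <- colMeans(abs(Xw))
    dXw <- Xw[-1, , drop = FALSE] - Xw[-width, , drop = FALSE]
    out[, (ch - 1) * 8 + 1:8] <- cbind(mav, c(0, diff(mav)), colSums(abs(dXw)),
                                       t(burg_ar(Xw, 4)),
                                       zero_crossings(Xw, zc_eps))
  }
  for (ax in 1:6) {
    Xw <- matrix(imu_seg[ax, idx], width)
    dXw <- Xw[-1, , drop = FALSE] - Xw[-width, , drop = FALSE]
    out[, 64 + (ax - 1) * 2 + 1:2] <- cbind(colMeans(abs(Xw)), colSums(abs(dXw)))
  }
  attr(out, "window_ids") <- keep
  out
}

#' Featurize a whole cohort
#'
#' Preprocesses every recording, trims it to its active segment and
#' extracts fused features. Segments come from the planted ground truth
#' (`segment_source = "truth"`, the default for synthetic cohorts) or from
#' the TKEO detector with ground-truth fallback on ambiguous trials
#' (`"detect"`).
#'
#' @param cohort as returned by [generate_cohort()].
#' @param segment_source `"truth"` or `"detect"`.
#' @param window_stride keep every `window_stride`-th window (1 keeps
#'   all); a runtime knob for large experiments.
#' @return object of class `feature_matrix`: list with `values`
#'   (rows x 76), `labels` (gesture ids) and `provenance` (data frame with
#'   subject, gesture, position, repetition, window).
#' @export
featurize_cohort <- function(cohort, segment_source = c("truth", "detect"),
                             window_stride = 1L) {
  segment_source <- match.arg(segment_source)
  vals <- list(); prov <- list(); i <- 1L
  for (sub in cohort$subjects) {
    for (rec in sub$recordings) {
      rec <- preprocess_recording(rec)
      if (segment_source == "detect") {
        seg <- tryCatch(detect_recording(rec), error = function(e) NULL)
        if (is.null(seg) || seg$status != "auto")
          seg <- list(onset_idx = rec$true_onset, offset_idx = rec$true_offset)
      } else {
        seg <- list(onset_idx = rec$true_onset, offset_idx = rec$true_offset)
      }
      trimmed <- apply_segment(seg, rec$emg, rec$imu)
      f <- featurize_segment(trimmed$emg, trimmed$imu, window_stride = window_stride)
      vals[[i]] <- f
      prov[[i]] <- data.frame(subject = rec$subject_id, gesture = rec$gesture_id,
                              position = rec$position_id, repetition = rec$repetition,
                              window = attr(f, "window_ids"))
      i <- i + 1L
    }
  }
  provenance <- do.call(rbind, prov)
  structure(list(values = do.call(rbind, vals),
                 labels = provenance$gesture,
                 provenance = provenance,
                 feature_names = feature_names("fused")),
            class = "feature_matrix")
}

# column indices of a modality inside the fused 76-column layout
modality_columns <- function(modality = c("fused", "emg", "imu")) {
  switch(match.arg(modality), emg = 1:64, imu = 65:76, fused = 1:76)
}
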