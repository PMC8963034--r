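#' Muscle-activity onset/offset detection
#'
#' TKEO conditioning and a peak-referenced double-threshold detector.
#' Each EMG channel is passed through the Teager-Kaiser energy operator,
#' low-passed at 50 Hz and rectified; the rectified energies are averaged
#' across channels and smoothed with a forward 60-sample RMS window. The
#' onset threshold is 20% of the mean of the local maxima that exceed 10%
#' of the global maximum; the offset threshold is 60% of the onset
#' threshold. Recordings where more than one supra-threshold region
#' survives are flagged `ambiguous` and all candidate regions returned,
#' mirroring the manual-review fallback of the original protocol.
#'
#' @name onset
NULL

#' Teager-Kaiser energy operator
#'
#' `psi(x_i) = x_i^2 - x_{i+1} * x_{i-1}` for interior samples; the two
#' endpoints are set to 0 (they lie in rest periods in this protocol).
#'
#' @param x numeric vector, length >= 3.
#' @return numeric vector, same length.
#' @export
tkeo <- function(x) {
  n <- length(x)
  if (n < 3) stop("TKEO needs at least 3 samples")
  c(0, x[2:(n - 1)]^2 - x[3:n] * x[1:(n - 2)], 0)
}

#' Condition EMG channels for onset detection
#'
#' Per channel: TKEO, 4th-order Butterworth low-pass at 50 Hz (zero-phase),
#' then full-wave rectification. Output is elementwise nonnegative.
#'
#' @param emg 8 x N matrix of filtered EMG at `rate` Hz.
#' @param rate sampling rate, Hz.
#' @return 8 x N nonnegative matrix of per-channel energies.
#' @export
condition_channels <- function(emg, rate = 200) {
  stopifnot(is.matrix(emg))
  lp <- butter_design(4, 50, rate, "lowpass")
  psi <- t(apply(emg, 1, function(ch) abs(filtfilt(lp, tkeo(ch)))))
  dimnames(psi) <- dimnames(emg)
  psi
}

#' Average conditioned energy across channels
#'
#' @param psi_channels channels x N nonnegative matrix.
#' @return length-N vector, the per-sample mean across channels.
#' @export
average_channels <- function(psi_channels) {
  stopifnot(is.matrix(psi_channels))
  if (nrow(psi_channels) < 1 || ncol(psi_channels) < 1) stop("empty input")
  colMeans(psi_channels)
}

#' Forward RMS smoothing
#'
#' `psi_rms(i) = sqrt(mean(psi_avg[i:(i + W - 1)]^2))`; the window is
#' forward-looking, so the output has length `N - W + 1` and index `i`
#' is attributed to the window start.
#'
#' @param psi_avg nonnegative vector.
#' @param W window size in samples (default 60).
#' @return vector of length `length(psi_avg) - W + 1`.
#' @export
rms_smooth <- function(psi_avg, W = 60) {
  n <- length(psi_avg)
  if (W < 1) stop("W must be >= 1")
  if (n < W) stop("input shorter than the RMS window")
  cs <- c(0, cumsum(psi_avg^2))
  sqrt((cs[(W + 1):(n + 1)] - cs[1:(n - W + 1)]) / W)
}

# strict local maxima; plateaus resolved to their first index
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1
      if (j <= n - 1 && x[j + 1] < x[j]) idx <- c(idx, i)
      i <- j + 1
    } else i <- i + 1
  }
  idx
}

#' Double-threshold active-region detection
#'
#' See the module description for the threshold rule. Onset is the first
#' index at or above the onset threshold; the region then extends while
#' the signal stays at or above the offset threshold, and the offset is
#' the last index of that region. Disjoint additional regions (detected
#' the same way) mark the trial `ambiguous`.
#'
#' @param psi_rms smoothed energy envelope.
#' @return object of class `active_segment`: list with `onset_idx`,
#'   `offset_idx` (indices into `psi_rms`), `status` (`"auto"` or
#'   `"ambiguous"`), `onset_threshold`, `offset_threshold`, and
#'   `candidates` (k x 2 matrix of all detected regions).
#' @export
detect_active_region <- function(psi_rms) {
  if (length(psi_rms) < 3 || max(psi_rms) <= 0)
    stop("no activity detectable: envelope is empty or non-positive")
  peaks <- local_maxima(psi_rms)
  peaks <- peaks[psi_rms[peaks] > 0.10 * max(psi_rms)]
  if (length(peaks) == 0) peaks <- which.max(psi_rms)
  onset_thr <- 0.20 * mean(psi_rms[peaks])
  offset_thr <- 0.60 * onset_thr

  above_on <- psi_rms >= onset_thr
  above_off <- psi_rms >= offset_thr
  regions <- matrix(integer(0), 0, 2)
  i <- 1L
  n <- length(psi_rms)
  while (i <= n) {
    if (above_on[i]) {
      on <- i
      j <- i
      while (j < n && above_off[j + 1]) j <- j + 1L
      regions <- rbind(regions, c(as.integer(on), as.integer(j)))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (nrow(regions) == 0)
    stop("no activity detectable: envelope never crosses the onset threshold")
  status <- if (nrow(regions) > 1) "ambiguous" else "auto"
  main <- regions[which.max(vapply(seq_len(nrow(regions)),
                                   function(r) max(psi_rms[regions[r, 1]:regions[r, 2]]),
                                   0)), ]
  structure(list(onset_idx = as.integer(main[1]), offset_idx = as.integer(main[2]),
                 status = status,
                 onset_threshold = onset_thr, offset_threshold = offset_thr,
                 candidates = regions),
            class = "active_segment")
}

#' Trim both modalities to an active segment
#'
#' @param seg an `active_segment` (or a list with `onset_idx`,
#'   `offset_idx` on the 200 Hz timeline).
#' @param emg 8 x N matrix.
#' @param imu 6 x N matrix on the same timeline.
#' @return list with `emg` (8 x L) and `imu` (6 x L), where
#'   `L = offset_idx - onset_idx + 1` (inclusive convention).
#' @export
apply_segment <- function(seg, emg, imu) {
  on <- seg$onset_idx; off <- seg$offset_idx
  if (on < 1 || off > ncol(emg) || off > ncol(imu) || on >= off)
    stop("segment indices out of bounds or inverted")
  list(emg = emg[, on:off, drop = FALSE], imu = imu[, on:off, drop = FALSE])
}

#' Detect the active region of a preprocessed recording
#'
#' Convenience wrapper running the whole chain on a recording that has
#' been through [preprocess_recording()]: conditioning, channel average,
#' RMS smoothing and double-threshold detection. Indices are mapped back
#' to the raw 200 Hz timeline without lag compensation (the RMS window is
#' forward-looking by construction).
#'
#' @param rec preprocessed recording.
#' @param W RMS window in samples.
#' @return `active_segment`.
#' @export
detect_recording <- function(rec, W = 60) {
  psi <- condition_channels(rec$emg, rec$emg_rate)
  detect_active_region(rms_smooth(average_channels(psi), W))
}
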