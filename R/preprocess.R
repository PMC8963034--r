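#' Signal conditioning and resampling
#'
#' Brings raw EMG and IMU streams onto a common, filtered 200 Hz timeline:
#' EMG is demeaned, 60 Hz-notched and high-passed at 20 Hz; IMU axes are
#' band-passed 0.2-15 Hz; IMU is then upsampled to the EMG grid with a
#' cubic spline. All filtering is zero-phase (forward-backward), see
#' [filtfilt()].
#'
#' @name preprocess
NULL

#' Filter raw EMG
#'
#' Per channel: subtract the channel mean (DC offset), apply a 60 Hz notch
#' (Q = 30), then a 4th-order Butterworth high-pass at 20 Hz.
#'
#' @param emg 8 x N matrix sampled at `rate` Hz.
#' @param rate sampling rate, Hz.
#' @return filtered matrix, same shape.
#' @export
filter_emg <- function(emg, rate = 200) {
  stopifnot(is.matrix(emg))
  if (ncol(emg) <= 12)
    stop("EMG record too short to filter (need > 3 x filter order samples)")
  notch <- notch_design(60, rate, Q = 30)
  hp <- butter_design(4, 20, rate, "highpass")
  out <- emg - rowMeans(emg)
  out <- filtfilt_rows(notch, out)
  filtfilt_rows(hp, out)
}

#' Filter raw IMU
#'
#' Per axis 4th-order Butterworth band-pass, 0.2-15 Hz.
#'
#' @param imu 6 x M matrix (3 accelerometer + 3 gyroscope axes) at `rate` Hz.
#' @param rate sampling rate, Hz.
#' @return filtered matrix, same shape.
#' @export
filter_imu <- function(imu, rate = 50) {
  stopifnot(is.matrix(imu))
  if (ncol(imu) <= 24)
    stop("IMU record too short to filter (need > 3 x filter order samples)")
  bp <- butter_design(4, c(0.2, 15), rate, "bandpass")
  filtfilt_rows(bp, imu)
}

#' Upsample IMU onto the EMG sample grid
#'
#' Cubic-spline interpolation from `from_rate` to `to_rate`. Values at the
#' original sample instants are reproduced exactly; the output has
#' `ratio * M` samples so the two modalities share index arithmetic
#' (the final `ratio - 1` samples extrapolate the last spline segment by
#' less than one IMU sample period).
#'
#' @param imu 6 x M matrix at `from_rate` Hz.
#' @param from_rate,to_rate sampling rates, Hz; `to_rate` must be an
#'   integer multiple of `from_rate`.
#' @return 6 x (ratio * M) matrix at `to_rate` Hz.
#' @export
upsample_imu <- function(imu, from_rate = 50, to_rate = 200) {
  stopifnot(is.matrix(imu))
  m <- ncol(imu)
  if (m < 4) stop("need at least 4 IMU samples for cubic-spline upsampling")
  ratio <- to_rate / from_rate
  if (ratio != round(ratio)) stop("to_rate must be an integer multiple of from_rate")
  t_in <- (seq_len(m) - 1) / from_rate
  t_out <- (seq_len(ratio * m) - 1) / to_rate
  out <- matrix(0, nrow(imu), length(t_out))
  for (i in seq_len(nrow(imu)))
    out[i, ] <- spline(t_in, imu[i, ], xout = t_out, method = "fmm")$y
  out
}

#' Preprocess one recording
#'
#' Runs [filter_emg()], [filter_imu()] and [upsample_imu()] and returns the
#' recording with `emg` and a 6 x N `imu` element on the common 200 Hz grid.
#'
#' @param rec a `raw_recording`.
#' @return the recording, with filtered `emg` and upsampled `imu` added.
#' @export
preprocess_recording <- function(rec) {
  rec$emg <- filter_emg(rec$emg, rec$emg_rate)
  imu <- rbind(rec$accel, rec$gyro)
  imu <- filter_imu(imu, rec$imu_rate)
  rec$imu <- upsample_imu(imu, rec$imu_rate, rec$emg_rate)[, seq_len(ncol(rec$emg)), drop = FALSE]
  rec
}
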