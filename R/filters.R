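#' IIR filter design and zero-phase filtering
#'
#' Minimal Butterworth / notch design used throughout the pipeline. Filters
#' are designed as zero-pole-gain systems via the bilinear transform and
#' converted to transfer-function coefficients; filtering runs in compiled
#' code. Zero-phase (forward-backward) application with odd-reflection
#' padding is the package default: the pipeline is offline and a causal
#' filter would bias detected onset indices.
#'
#' @name filters
NULL

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a Butterworth filter
#'
#' @param order filter order (of the analog prototype; a band-pass design
#'   has `2 * order` coefficients).
#' @param cutoffs_hz one cutoff (low/high-pass) or two (band-pass), Hz.
#' @param fs sampling rate, Hz.
#' @param type one of `"lowpass"`, `"highpass"`, `"bandpass"`.
#' @return list with numerator `b` and denominator `a` coefficients (and a
#'   cached steady-state `zi` used by [filtfilt()]).
#' @export
butter_design <- function(order, cutoffs_hz, fs, type = c("lowpass", "highpass", "bandpass")) {
  type <- match.arg(type)
  key <- paste("butter", order, paste(cutoffs_hz, collapse = "-"), fs, type)
  cached <- .design_cache[[key]]
  if (!is.null(cached)) return(cached)
  stopifnot(order >= 1, all(cutoffs_hz > 0), all(cutoffs_hz < fs / 2))
  if (type == "bandpass" && length(cutoffs_hz) != 2)
    stop("bandpass needs two cutoffs")
  if (type != "bandpass" && length(cutoffs_hz) != 1)
    stop(type, " needs one cutoff")

  # analog Butterworth prototype (unit cutoff), poles only, gain 1
  k_idx <- seq_len(order)
  p <- exp(1i * pi * (2 * k_idx + order - 1) / (2 * order))
  z <- complex(0)
  k <- 1

  fs2 <- 2 * fs
  warped <- fs2 * tan(pi * cutoffs_hz / fs)  # prewarp

  if (type == "lowpass") {
    w0 <- warped
    p <- p * w0
    k <- k * w0^order
  } else if (type == "highpass") {
    w0 <- warped
    k <- k * Re(prod(-p))    # = 1 for Butterworth, kept general
    p <- w0 / p
    z <- rep(0 + 0i, order)
  } else {
    w0 <- sqrt(prod(warped))
    bw <- warped[2] - warped[1]
    ph <- p * bw / 2
    p <- c(ph + sqrt(ph^2 - w0^2), ph - sqrt(ph^2 - w0^2))
    z <- rep(0 + 0i, order)
    k <- k * bw^order
  }

  # bilinear transform
  pd <- (fs2 + p) / (fs2 - p)
  zd <- (fs2 + z) / (fs2 - z)
  k <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))

  b <- Re(k * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  out <- list(b = b, a = a, zi = lfilter_zi(b, a))
  .design_cache[[key]] <- out
  out
}

# designs are pure functions of their parameters; memoize them (with the
# steady-state initial conditions) since preprocessing redesigns the same
# few filters for every trial
.design_cache <- new.env(parent = emptyenv())

#' Design a second-order IIR notch filter
#'
#' Standard biquad notch; quality factor defaults to 30, a narrow
#' power-line notch.
#'
#' @param f0 notch frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param Q quality factor (f0 / bandwidth).
#' @return list with `b`, `a`.
#' @export
notch_design <- function(f0, fs, Q = 30) {
  stopifnot(f0 > 0, f0 < fs / 2, Q > 0)
  key <- paste("notch", f0, fs, Q)
  cached <- .design_cache[[key]]
  if (!is.null(cached)) return(cached)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  out <- list(b = b / a[1], a = a / a[1])
  out$zi <- lfilter_zi(out$b, out$a)
  .design_cache[[key]] <- out
  out
}

# steady-state initial filter state for a step input of height 1
# (same construction as the classic filtfilt initialization)
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  b <- b / a[1]; a <- a / a[1]
  n <- nf - 1
  if (n == 0) return(numeric(0))
  comp <- matrix(0, n, n)       # companion matrix of a, transposed
  comp[1, ] <- -a[-1]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  IminusA <- diag(n) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(IminusA, B))
}

#' Zero-phase filtering
#'
#' Forward-backward application of an IIR filter with odd-reflection
#' padding (3 x filter order on each side) and steady-state initial
#' conditions, so transients at the record edges are suppressed.
#'
#' @param filt list with `b`, `a` (as returned by [butter_design()] or
#'   [notch_design()]).
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt <- function(filt, x) {
  b <- filt$b; a <- filt$a
  nf <- max(length(a), length(b))
  padlen <- 3 * (nf - 1)
  n <- length(x)
  if (n <= padlen)
    stop("signal too short for this filter: need more than ", padlen, " samples")
  ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- filt$zi %||% lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir_filter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

# apply a zero-phase filter to every row of a channels x samples matrix
filtfilt_rows <- function(filt, m) {
  out <- t(apply(m, 1, function(r) filtfilt(filt, r)))
  dimnames(out) <- dimnames(m)
  out
}
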