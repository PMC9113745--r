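#' Zero-phase bandpass filtering
#'
#' Two designs are used in the pipeline. The wide 0.3-35 Hz preprocessing
#' band uses a linear-phase FIR (Hamming-window design) applied
#' forward-backward, so slow-oscillation morphology is not phase-distorted.
#' Narrow event bands (0.3-4, 0.5-4, spindle fc +/- 2 Hz) use a 2nd-order
#' Butterworth applied forward-backward (effective 4th order), the usual
#' choice for narrowband filter-Hilbert work.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param lo,hi band edges, Hz. `lo = 0` gives a low-pass, `hi = Inf` a
#'   high-pass.
#' @param type "fir" or "butter".
#' @param order filter order; default 660 taps for FIR, 2 for Butterworth.
#' @return filtered vector, same length as `x`.
#' @export
bp_filter <- function(x, fs, lo, hi, type = c("butter", "fir"), order = NULL) {
  type <- match.arg(type)
  ny <- fs / 2
  if (lo < 0 || hi <= lo) stop("bad band edges")
  if (hi >= ny) hi <- Inf
  if (type == "fir") {
    if (is.null(order)) order <- 660L
    if (order %% 2L == 1L) order <- order + 1L  # even order -> symmetric taps
    b <- if (lo <= 0) {
      signal::fir1(order, hi / ny, type = "low")
    } else if (!is.finite(hi)) {
      signal::fir1(order, lo / ny, type = "high")
    } else {
      signal::fir1(order, c(lo, hi) / ny, type = "pass")
    }
    as.numeric(signal::filtfilt(signal::Ma(b), x))
  } else {
    if (is.null(order)) order <- 2L
    flt <- if (lo <= 0) {
      signal::butter(order, hi / ny, type = "low")
    } else if (!is.finite(hi)) {
      signal::butter(order, lo / ny, type = "high")
    } else {
      signal::butter(order, c(lo, hi) / ny, type = "pass")
    }
    as.numeric(signal::filtfilt(flt, x))
  }
}

#' Analytic signal via the Hilbert transform
#'
#' FFT implementation: positive frequencies doubled, negative zeroed.
#'
#' @param x real vector.
#' @return complex vector `x + i * H(x)`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase in degrees, 0 = oscillation positive peak
#'
#' For a narrowband signal `A(t) cos(theta(t))` the analytic-signal argument
#' is `theta`; 0 deg at the positive peak, 180 deg at the negative peak,
#' 180-270 deg on the rising slope.
#'
#' @param x narrowband real vector.
#' @return phase per sample in `[0, 360)` degrees.
#' @export
inst_phase_deg <- function(x) {
  (Arg(analytic_signal(x)) * 180 / pi) %% 360
}

#' Resample a signal to a new rate
#'
#' Rational-factor polyphase resampling (anti-aliased).
#'
#' @param x numeric vector.
#' @param fs_in,fs_out rates in Hz.
#' @return resampled vector of length ~ `length(x) * fs_out / fs_in`.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  r <- fs_out / fs_in
  # small rational approximation of the ratio
  pq <- best_rational(r)
  y <- signal::resample(x, pq[1], pq[2])
  n_out <- round(length(x) * r)
  length(y) <- n_out
  y[is.na(y)] <- 0
  y
}

best_rational <- function(r, max_den = 1000L) {
  # continued-fraction approximation
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  x <- r
  repeat {
    a <- floor(x)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - r) < 1e-12) break
    if (x == a) break
    x <- 1 / (x - a)
  }
  c(as.integer(p1), as.integer(q1))
}

moving_average <- function(x, w) {
  # centered moving average, window w samples (odd enforced);
  # edges use truncated windows
  if (w <= 1) return(x)
  if (w %% 2 == 0) w <- w + 1
  n <- length(x)
  half <- (w - 1) / 2
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# contiguous runs of TRUE in a logical vector -> matrix [start, end] (inclusive)
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}
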