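#' Spindle-detector configuration
#'
#' Wavelet detector settings. Thresholds are multiples of the mean smoothed
#' wavelet-coefficient magnitude over the analyzed (clean, in-stage)
#' samples, so detection is invariant to global amplitude rescaling.
#'
#' @param center_freq wavelet center frequency, Hz (11 slow / 15 fast).
#' @param wavelet_cycles Morlet cycle count (width); 7 separates the 11 and
#'   15 Hz targets.
#' @param smooth_window temporal smoothing window, seconds.
#' @param core_thresh,flank_thresh threshold multiples of the mean.
#' @param core_min_dur,flank_min_dur minimum durations, seconds.
#' @param max_dur maximal event duration, seconds.
#' @param merge_gap events closer than this are merged (unless the merged
#'   event would exceed `max_dur`).
#' @return list of class `spindle_detector_config`.
#' @export
spindle_detector_config <- function(center_freq = 15, wavelet_cycles = 7,
                                    smooth_window = 0.1, core_thresh = 4.5,
                                    flank_thresh = 2, core_min_dur = 0.3,
                                    flank_min_dur = 0.5, max_dur = 3,
                                    merge_gap = 0.5) {
  if (core_thresh <= flank_thresh) stop("core_thresh must exceed flank_thresh")
  if (!(core_min_dur < flank_min_dur && flank_min_dur < max_dur))
    stop("need core_min_dur < flank_min_dur < max_dur")
  structure(list(center_freq = center_freq, wavelet_cycles = wavelet_cycles,
                 smooth_window = smooth_window, core_thresh = core_thresh,
                 flank_thresh = flank_thresh, core_min_dur = core_min_dur,
                 flank_min_dur = flank_min_dur, max_dur = max_dur,
                 merge_gap = merge_gap),
            class = "spindle_detector_config")
}

#' Complex Morlet wavelet coefficient magnitude
#'
#' FFT-based convolution of the signal with a complex Morlet wavelet
#' (Gaussian envelope of `cycles / (2 pi fc)` SD), followed by temporal
#' smoothing with a `smooth_window`-second moving average.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param cfg a [spindle_detector_config()].
#' @param smooth apply the moving-average smoothing (default TRUE).
#' @return nonnegative magnitude series, same length as `x`.
#' @export
cwt_magnitude <- function(x, fs, cfg = spindle_detector_config(),
                          smooth = TRUE) {
  fc <- cfg$center_freq
  if (fc >= fs / 2) stop("center frequency at or above Nyquist")
  sd_t <- cfg$wavelet_cycles / (2 * pi * fc)
  tt <- seq(-4 * sd_t, 4 * sd_t, by = 1 / fs)
  kern <- exp(2i * pi * fc * tt) * exp(-tt^2 / (2 * sd_t^2))
  kern <- kern / sqrt(sum(Mod(kern)^2))
  n <- length(x)
  nk <- length(kern)
  N <- stats::nextn(n + nk - 1L, 2)
  Y <- stats::fft(stats::fft(c(x, numeric(N - n))) *
                    stats::fft(c(kern, numeric(N - nk))), inverse = TRUE) / N
  off <- (nk - 1L) %/% 2L
  mag <- Mod(Y[(off + 1L):(off + n)])
  if (smooth) mag <- moving_average(mag, round(cfg$smooth_window * fs))
  mag
}

# candidate intervals: flank runs (>= flank_thresh x mean, >= flank_min_dur)
# containing a core run (>= core_thresh x mean, >= core_min_dur)
spindle_candidates <- function(mag, mask, fs, cfg) {
  mu <- mean(mag[mask])
  flank <- (mag > cfg$flank_thresh * mu) & mask
  core <- (mag > cfg$core_thresh * mu) & mask
  runs <- true_runs(flank)
  keep <- logical(nrow(runs))
  min_flank <- round(cfg$flank_min_dur * fs)
  min_core <- round(cfg$core_min_dur * fs)
  for (i in seq_len(nrow(runs))) {
    if (runs[i, 2] - runs[i, 1] + 1L < min_flank) next
    seg <- core[runs[i, 1]:runs[i, 2]]
    cr <- true_runs(seg)
    if (nrow(cr) && any(cr[, 2] - cr[, 1] + 1L >= min_core)) keep[i] <- TRUE
  }
  runs[keep, , drop = FALSE]
}

merge_candidates <- function(cand, fs, cfg) {
  if (nrow(cand) < 2) return(cand)
  max_len <- round(cfg$max_dur * fs)
  gap_len <- round(cfg$merge_gap * fs)
  out <- cand[1, , drop = FALSE]
  for (i in 2:nrow(cand)) {
    gap <- cand[i, 1] - out[nrow(out), 2] - 1L
    merged_len <- cand[i, 2] - out[nrow(out), 1] + 1L
    if (gap <= gap_len && merged_len <= max_len) {
      out[nrow(out), 2] <- cand[i, 2]
    } else {
      out <- rbind(out, cand[i, , drop = FALSE])
    }
  }
  out
}

#' Detect sleep spindles
#'
#' Wavelet detector: intervals of the temporally smoothed Morlet
#' coefficient magnitude exceeding `flank_thresh` x mean for at least
#' `flank_min_dur` and containing a stretch above `core_thresh` x mean for
#' at least `core_min_dur`. Neighbouring intervals closer than `merge_gap`
#' are merged unless the merged event would exceed `max_dur`; events longer
#' than `max_dur` are rejected. The mean is taken over the analyzed
#' (masked) samples only.
#'
#' @param x one channel's preprocessed signal.
#' @param fs sampling rate, Hz.
#' @param mask logical per-sample mask of clean in-stage samples.
#' @param cfg a [spindle_detector_config()].
#' @param channel channel label stored in the output.
#' @return data.frame of events: channel, start/end (samples), start_s,
#'   stop_s, peak_time, duration, amplitude (uV peak-to-peak), isa,
#'   obs_freq, chirp.
#' @export
detect_spindles <- function(x, fs, mask = NULL,
                            cfg = spindle_detector_config(), channel = 1L) {
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  if (!any(mask)) stop("mask selects no samples")
  mag <- cwt_magnitude(x, fs, cfg)
  mu <- mean(mag[mask])
  cand <- spindle_candidates(mag, mask, fs, cfg)
  cand <- merge_candidates(cand, fs, cfg)
  if (nrow(cand)) {
    lens <- cand[, 2] - cand[, 1] + 1L
    cand <- cand[lens <= round(cfg$max_dur * fs), , drop = FALSE]
  }
  bp <- bp_filter(x, fs, cfg$center_freq - 2, cfg$center_freq + 2)
  ev <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand[i, 1]; e <- cand[i, 2]
    wf <- bp[s:e]
    pk <- max_p2p(wf)
    zc <- chirp_from_zero_crossings(wf, fs)
    ev[[i]] <- data.frame(
      channel = channel, start = s, end = e,
      start_s = (s - 1) / fs, stop_s = (e - 1) / fs,
      peak_time = (s - 1 + pk$center) / fs,
      duration = (e - s + 1) / fs,
      amplitude = pk$p2p,
      isa = sum(mag[s:e] / mu) / fs,
      obs_freq = zc["obs_freq"], chirp = zc["chirp"])
  }
  if (length(ev)) do.call(rbind, ev) else empty_spindle_events()
}

empty_spindle_events <- function() {
  data.frame(channel = integer(0), start = integer(0), end = integer(0),
             start_s = numeric(0), stop_s = numeric(0),
             peak_time = numeric(0), duration = numeric(0),
             amplitude = numeric(0), isa = numeric(0),
             obs_freq = numeric(0), chirp = numeric(0))
}

# maximal peak-to-peak amplitude between consecutive local extrema;
# returns the p2p value and the (0-based) center sample of that cycle
max_p2p <- function(wf) {
  n <- length(wf)
  if (n < 3) return(list(p2p = max(wf) - min(wf), center = (n - 1) / 2))
  d <- diff(wf)
  ext <- which(d[-1] * d[-length(d)] <= 0 & (d[-1] != 0 | d[-length(d)] != 0)) + 1L
  if (length(ext) < 2) return(list(p2p = max(wf) - min(wf), center = (n - 1) / 2))
  p2p <- abs(diff(wf[ext]))
  j <- which.max(p2p)
  list(p2p = p2p[j], center = (ext[j] + ext[j + 1]) / 2 - 1)
}

#' Implied frequency and chirp from zero crossings
#'
#' The event waveform (already bandpassed to the detection band) is scanned
#' for zero crossings; the implied frequency of an interval set is
#' `1 / (2 x mean crossing-to-crossing interval)`. Chirp is the implied
#' frequency of the second half of the event minus that of the first half
#' (negative = deceleration).
#'
#' @param wf bandpassed event waveform.
#' @param fs sampling rate, Hz.
#' @param min_crossings minimum crossings per half; below it chirp is NA.
#' @return named numeric: obs_freq, chirp (Hz).
#' @export
chirp_from_zero_crossings <- function(wf, fs, min_crossings = 4) {
  n <- length(wf)
  s <- sign(wf)
  s[s == 0] <- 1
  idx <- which(diff(s) != 0)
  if (length(idx) < 2)
    return(c(obs_freq = NA_real_, chirp = NA_real_))
  # linear interpolation of crossing times (in samples, 0-based)
  tz <- (idx - 1) + wf[idx] / (wf[idx] - wf[idx + 1])
  implied <- function(t) {
    if (length(t) < 2) return(NA_real_)
    fs / (2 * mean(diff(t)))
  }
  obs <- implied(tz)
  mid <- (n - 1) / 2
  f1 <- if (sum(tz <= mid) >= min_crossings) implied(tz[tz <= mid]) else NA_real_
  f2 <- if (sum(tz > mid) >= min_crossings) implied(tz[tz > mid]) else NA_real_
  c(obs_freq = obs, chirp = f2 - f1)
}

#' Band-ratio quality control of detected spindles
#'
#' A putative spindle is kept only if its relative power increase in the
#' detection (sigma) band — event-window power over the stage-mean power —
#' is at least as large as the relative increase in each of the delta
#' (0.5-4), theta (4-8) and beta (15-30 Hz) bands. Event-window power uses
#' a single Tukey-tapered periodogram of the event; stage means use
#' Welch segments over the clean in-stage samples.
#'
#' @param events data.frame from [detect_spindles()].
#' @param x the signal the events were detected on.
#' @param fs sampling rate.
#' @param mask analyzed-sample mask.
#' @param center_freq detection target frequency (sigma band =
#'   `center_freq` +/- 2 Hz).
#' @return the retained subset of `events`.
#' @export
qc_spindles <- function(events, x, fs, mask = NULL, center_freq = 15) {
  if (nrow(events) == 0) return(events)
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                sigma = c(center_freq - 2, center_freq + 2),
                beta = c(15, 30))
  stage_p <- stage_band_power(x, fs, mask, bands)
  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    wf <- x[events$start[i]:events$end[i]]
    evp <- window_band_power(wf, fs, bands)
    ratio <- evp / stage_p
    keep[i] <- all(ratio["sigma"] >= ratio[c("delta", "theta", "beta")])
  }
  events[keep, , drop = FALSE]
}

# single Tukey(0.5)-tapered periodogram band powers of a short window
window_band_power <- function(wf, fs, bands) {
  n <- length(wf)
  w <- tukey_window(n, 0.5)
  X <- stats::fft(wf * w)
  p <- Mod(X)^2 / (fs * sum(w^2))
  nf <- floor(n / 2)
  f <- (seq_len(nf + 1) - 1) * fs / n
  p <- p[seq_len(nf + 1)]
  last_double <- if (n %% 2 == 0) nf else nf + 1  # Nyquist bin not doubled
  p[2:last_double] <- 2 * p[2:last_double]
  vapply(bands, function(b) {
    sel <- f >= b[1] & f <= b[2]
    if (!any(sel)) return(0)
    sum(p[sel]) * fs / n
  }, 0)
}

# mean band power over 4-s Welch segments restricted to masked samples
stage_band_power <- function(x, fs, mask, bands) {
  seg <- round(4 * fs)
  runs <- true_runs(mask)
  acc <- matrix(0, 0, length(bands))
  for (r in seq_len(nrow(runs))) {
    i0 <- runs[r, 1]
    while (i0 + seg - 1L <= runs[r, 2]) {
      acc <- rbind(acc, window_band_power(x[i0:(i0 + seg - 1L)], fs, bands))
      i0 <- i0 + seg %/% 2L
    }
  }
  if (nrow(acc) == 0)
    acc <- matrix(window_band_power(x[mask], fs, bands), 1)
  stats::setNames(colMeans(acc), names(bands))
}

#' Per-channel spindle summary metrics
#'
#' @param events QC-passed events of one channel/target.
#' @param minutes minutes of analyzed sleep.
#' @return one-row data.frame: n_events, density (per minute) and means of
#'   amplitude, isa, duration, obs_freq, chirp (NA when no events).
#' @export
spindle_metrics <- function(events, minutes) {
  if (minutes <= 0) stop("minutes analyzed must be positive")
  n <- nrow(events)
  mean_or_na <- function(v) if (n) mean(v, na.rm = TRUE) else NA_real_
  data.frame(n_events = n, density = n / minutes,
             amplitude = mean_or_na(events$amplitude),
             isa = mean_or_na(events$isa),
             duration = mean_or_na(events$duration),
             obs_freq = mean_or_na(events$obs_freq),
             chirp = mean_or_na(events$chirp))
}
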