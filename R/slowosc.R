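#' Slow-oscillation detector configuration
#'
#' Zero-crossing detector on the 0.3-4 Hz filtered signal. A candidate SO
#' starts at a positive-to-negative zero crossing; its negative half-wave
#' (to the next rising crossing) must last 0.3-1.5 s and the following
#' positive half-wave at most 1 s. Amplitude filtering is either absolute
#' (negative peak below `abs_neg_thresh` and peak-to-peak above
#' `abs_p2p_thresh`) or adaptive (negative-peak magnitude and peak-to-peak
#' each above `adaptive_mult` times the candidate mean for that channel).
#'
#' @param band filter band, Hz.
#' @param neg_halfwave_dur allowed negative half-wave duration, seconds.
#' @param pos_halfwave_max maximal positive half-wave duration, seconds.
#' @param mode "adaptive" (default) or "absolute".
#' @param abs_neg_thresh absolute negative-peak threshold, microvolts (< 0).
#' @param abs_p2p_thresh absolute peak-to-peak threshold, microvolts.
#' @param adaptive_mult multiple of the candidate mean in adaptive mode.
#' @return list of class `so_detector_config`.
#' @export
so_detector_config <- function(band = c(0.3, 4),
                               neg_halfwave_dur = c(0.3, 1.5),
                               pos_halfwave_max = 1.0,
                               mode = c("adaptive", "absolute"),
                               abs_neg_thresh = -40, abs_p2p_thresh = 75,
                               adaptive_mult = 2) {
  mode <- match.arg(mode)
  if (any(neg_halfwave_dur <= 0) || pos_halfwave_max <= 0)
    stop("duration bounds must be positive")
  structure(list(band = band, neg_halfwave_dur = neg_halfwave_dur,
                 pos_halfwave_max = pos_halfwave_max, mode = mode,
                 abs_neg_thresh = abs_neg_thresh,
                 abs_p2p_thresh = abs_p2p_thresh,
                 adaptive_mult = adaptive_mult),
            class = "so_detector_config")
}

#' Detect slow oscillations
#'
#' @param x one channel's preprocessed signal, microvolts.
#' @param fs sampling rate, Hz.
#' @param mask logical mask of clean in-stage samples (candidates must lie
#'   fully inside it).
#' @param cfg an [so_detector_config()].
#' @param channel channel label for the output.
#' @return data.frame of events: channel, start/end samples, start_s,
#'   stop_s, neg_peak_time, neg_peak_amp, p2p_amp, duration, up_slope
#'   (uV/s, negative peak to next zero crossing).
#' @export
detect_so <- function(x, fs, mask = NULL, cfg = so_detector_config(),
                      channel = 1L) {
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  xf <- bp_filter(x, fs, cfg$band[1], cfg$band[2])
  s <- sign(xf)
  s[s == 0] <- 1
  dchg <- diff(s)
  down <- which(dchg < 0)   # positive-to-negative crossing (SO start)
  up <- which(dchg > 0)     # negative-to-positive crossing
  cand <- list()
  for (t0 in down) {
    t1 <- up[up > t0][1]
    if (is.na(t1)) break
    t2 <- down[down > t1][1]
    if (is.na(t2)) break
    neg_dur <- (t1 - t0) / fs
    pos_dur <- (t2 - t1) / fs
    if (neg_dur < cfg$neg_halfwave_dur[1] ||
        neg_dur > cfg$neg_halfwave_dur[2]) next
    if (pos_dur > cfg$pos_halfwave_max) next
    if (!all(mask[t0:t2])) next
    seg_neg <- xf[t0:t1]
    seg_pos <- xf[t1:t2]
    npk <- t0 + which.min(seg_neg) - 1L
    neg_amp <- min(seg_neg)
    p2p <- max(seg_pos) - neg_amp
    rise <- (t1 - npk) / fs
    cand[[length(cand) + 1L]] <- data.frame(
      channel = channel, start = t0, end = t2,
      start_s = (t0 - 1) / fs, stop_s = (t2 - 1) / fs,
      neg_peak = npk, neg_peak_time = (npk - 1) / fs,
      neg_peak_amp = neg_amp, p2p_amp = p2p,
      duration = (t2 - t0) / fs,
      up_slope = if (rise > 0) abs(neg_amp) / rise else NA_real_)
  }
  if (!length(cand)) {
    if (cfg$mode == "adaptive")
      warning("no SO candidates; adaptive means undefined")
    return(empty_so_events())
  }
  cand <- do.call(rbind, cand)
  if (cfg$mode == "absolute") {
    keep <- cand$neg_peak_amp < cfg$abs_neg_thresh &
      cand$p2p_amp > cfg$abs_p2p_thresh
  } else {
    keep <- abs(cand$neg_peak_amp) >
      cfg$adaptive_mult * mean(abs(cand$neg_peak_amp)) &
      cand$p2p_amp > cfg$adaptive_mult * mean(cand$p2p_amp)
  }
  cand[keep, , drop = FALSE]
}

empty_so_events <- function() {
  data.frame(channel = integer(0), start = integer(0), end = integer(0),
             start_s = numeric(0), stop_s = numeric(0),
             neg_peak = integer(0), neg_peak_time = numeric(0),
             neg_peak_amp = numeric(0), p2p_amp = numeric(0),
             duration = numeric(0), up_slope = numeric(0))
}

#' Per-channel slow-oscillation summary metrics
#'
#' @param events events of one channel from [detect_so()].
#' @param minutes minutes of analyzed sleep.
#' @return one-row data.frame: n_events, density, mean neg_peak_amp,
#'   p2p_amp, duration, up_slope.
#' @export
so_metrics <- function(events, minutes) {
  if (minutes <= 0) stop("minutes analyzed must be positive")
  n <- nrow(events)
  mean_or_na <- function(v) if (n) mean(v, na.rm = TRUE) else NA_real_
  data.frame(n_events = n, density = n / minutes,
             neg_peak_amp = mean_or_na(events$neg_peak_amp),
             p2p_amp = mean_or_na(events$p2p_amp),
             duration = mean_or_na(events$duration),
             up_slope = mean_or_na(events$up_slope))
}
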