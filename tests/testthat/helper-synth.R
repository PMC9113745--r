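# shared fixtures: built in code, small enough for fast tests

FS <- 200

# event-interval recall/precision between truth and detected tables
interval_recall <- function(truth, events) {
  if (nrow(truth) == 0) return(NA_real_)
  mean(vapply(seq_len(nrow(truth)), function(i)
    any(events$start <= truth$end[i] & events$end >= truth$start[i]), TRUE))
}

interval_precision <- function(truth, events) {
  if (nrow(events) == 0) return(NA_real_)
  mean(vapply(seq_len(nrow(events)), function(i)
    any(truth$start <= events$end[i] & truth$end >= events$start[i]), TRUE))
}

# short pink-noise background for detector tests
quick_background <- function(seconds = 600, rms = 20, seed = 1,
                             n_channels = 1) {
  make_background(background_spec(n_channels, seconds, fs = FS,
                                  one_over_f_slope = 2, rms = rms,
                                  seed = seed))
}

# spindle amplitude for an in-band SNR target: burst rms over its duration
# relative to the background's 11-15 Hz rms (0.433 = rms of a Hann-enveloped
# unit-amplitude sinusoid)
snr_amplitude <- function(bg_signal, snr = 4) {
  s <- stats::sd(bp_filter(bg_signal, FS, 11, 15))
  2 * snr * s / 0.433
}

circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
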