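#' Artifact-pipeline configuration
#'
#' Thresholds of the three-stage Hjorth artifact procedure: (1) bad-channel
#' flagging by within-epoch, cross-channel comparison (2 SD, >30% of
#' epochs), (2) per-channel outlier-epoch interpolation (4 SD, plus
#' absolute-amplitude and flat/clipped rules), (3) per-channel 4 SD flags
#' with global epoch dropping, repeated once.
#'
#' @param bad_channel_epoch_sd SD threshold of stage 1 (cross-channel).
#' @param bad_channel_fraction fraction of flagged epochs that makes a
#'   channel bad.
#' @param epoch_sd SD threshold of stage 2 (per channel, across epochs).
#' @param max_abs_amp absolute-amplitude limit, microvolts.
#' @param flat_clip_fraction maximal tolerated fraction of flat or clipped
#'   samples per epoch.
#' @param per_channel_sd SD threshold of stage 3.
#' @param final_pass_repeats how often stage 3 is repeated after its first
#'   pass.
#' @return list of class `artifact_config`.
#' @export
artifact_config <- function(bad_channel_epoch_sd = 2,
                            bad_channel_fraction = 0.30,
                            epoch_sd = 4, max_abs_amp = 500,
                            flat_clip_fraction = 0.10,
                            per_channel_sd = 4, final_pass_repeats = 1) {
  vals <- c(bad_channel_epoch_sd, bad_channel_fraction, epoch_sd,
            max_abs_amp, flat_clip_fraction, per_channel_sd)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(list(bad_channel_epoch_sd = bad_channel_epoch_sd,
                 bad_channel_fraction = bad_channel_fraction,
                 epoch_sd = epoch_sd, max_abs_amp = max_abs_amp,
                 flat_clip_fraction = flat_clip_fraction,
                 per_channel_sd = per_channel_sd,
                 final_pass_repeats = final_pass_repeats),
            class = "artifact_config")
}

# epochs x channels x 3 Hjorth array for the given epochs
hjorth_array <- function(rec, epochs, epoch_len = 30) {
  H <- array(NA_real_, c(length(epochs), nrow(rec$data), 3))
  for (k in seq_along(epochs)) {
    idx <- epoch_indices(epochs[k], rec$fs, epoch_len)
    idx <- idx[idx <= ncol(rec$data)]
    for (ch in seq_len(nrow(rec$data)))
      H[k, ch, ] <- hjorth(rec$data[ch, idx], rec$fs)
  }
  H
}

flat_clip_fraction_of <- function(x) {
  flat <- c(FALSE, diff(x) == 0)
  clip <- x >= max(x) | x <= min(x)
  # clipping only meaningful when the extreme is sustained
  mean(flat | (clip & (c(FALSE, diff(x) == 0) | c(diff(x) == 0, FALSE))))
}

#' Three-stage Hjorth artifact pipeline
#'
#' Statistics are computed separately within each sleep stage. Stage 1
#' flags channels whose per-epoch Hjorth parameters deviate from the
#' cross-channel mean by more than `bad_channel_epoch_sd` SD in over
#' `bad_channel_fraction` of epochs; such channels are spherical-spline
#' interpolated for all epochs. Stage 2 interpolates, per channel,
#' epochs beyond `epoch_sd` SD of that channel's epoch distribution, or
#' exceeding `max_abs_amp`, or flat/clipped beyond `flat_clip_fraction`.
#' Stage 3 re-flags per-channel outlier epochs at `per_channel_sd` SD and
#' drops every flagged epoch for all channels; it is repeated
#' `final_pass_repeats` more times. The returned annotation mask records
#' every action, so the retained epoch set is identical across channels.
#'
#' @param rec preprocessed recording (positions needed for interpolation).
#' @param ann a `stage_annotation` covering the recording.
#' @param cfg an [artifact_config()].
#' @param stages_to_clean stage labels to process (default all present).
#' @return list: `rec` (interpolated recording), `ann` (updated mask),
#'   `bad_channels` (stage-1 channels).
#' @export
artifact_pipeline <- function(rec, ann, cfg = artifact_config(),
                              stages_to_clean = NULL) {
  n_ch <- nrow(rec$data)
  n_ep <- length(ann$stages)
  if (ncol(ann$mask) != n_ch)
    ann$mask <- matrix("clean", n_ep, n_ch)
  if (is.null(stages_to_clean))
    stages_to_clean <- setdiff(unique(ann$stages), "?")
  all_bad <- integer(0)

  # --- stage 1: bad channels (within-epoch, cross-channel), per sleep stage
  for (st in stages_to_clean) {
    eps <- which(ann$stages == st)
    if (length(eps) < 2 || n_ch < 3) next
    H <- hjorth_array(rec, eps)
    flagged <- matrix(FALSE, length(eps), n_ch)
    for (k in seq_along(eps)) {
      for (p in 1:3) {
        v <- H[k, , p]
        if (anyNA(v)) next
        mu <- mean(v); s <- stats::sd(v)
        if (s == 0) next
        flagged[k, ] <- flagged[k, ] |
          abs(v - mu) > cfg$bad_channel_epoch_sd * s
      }
    }
    frac <- colMeans(flagged)
    all_bad <- union(all_bad, which(frac > cfg$bad_channel_fraction))
  }
  if (length(all_bad) > 0.25 * n_ch)
    stop("more than 25% of channels flagged bad; interpolation unreliable")
  if (length(all_bad)) {
    rec <- interpolate_spherical_spline(rec, all_bad)
    ann$mask[, all_bad] <- "interpolated"
  }

  # --- stage 2: per-channel outlier epochs -> interpolate
  for (st in stages_to_clean) {
    eps <- which(ann$stages == st)
    if (length(eps) < 3) next
    H <- hjorth_array(rec, eps)
    for (ch in seq_len(n_ch)) {
      bad_ep <- rep(FALSE, length(eps))
      for (p in 1:3) {
        v <- H[, ch, p]
        if (anyNA(v)) next
        mu <- mean(v); s <- stats::sd(v)
        if (s > 0) bad_ep <- bad_ep | abs(v - mu) > cfg$epoch_sd * s
      }
      for (k in seq_along(eps)) {
        idx <- epoch_indices(eps[k], rec$fs, ann$epoch_len)
        idx <- idx[idx <= ncol(rec$data)]
        x <- rec$data[ch, idx]
        if (max(abs(x)) > cfg$max_abs_amp) bad_ep[k] <- TRUE
        else if (flat_clip_fraction_of(x) > cfg$flat_clip_fraction)
          bad_ep[k] <- TRUE
      }
      if (any(bad_ep) && n_ch >= 5 && !is.null(rec$positions)) {
        for (k in which(bad_ep)) {
          idx <- epoch_indices(eps[k], rec$fs, ann$epoch_len)
          idx <- idx[idx <= ncol(rec$data)]
          rec <- interpolate_spherical_spline(rec, ch, samples = idx)
          if (ann$mask[eps[k], ch] == "clean")
            ann$mask[eps[k], ch] <- "interpolated"
        }
      } else if (any(bad_ep)) {
        # cannot interpolate (too few channels): defer to stage 3 dropping
        for (k in which(bad_ep)) ann$mask[eps[k], ] <- "dropped"
      }
    }
  }

  # --- stage 3: per-channel 4 SD flags -> drop epoch for all channels
  for (pass in seq_len(1 + cfg$final_pass_repeats)) {
    for (st in stages_to_clean) {
      eps <- which(ann$stages == st &
                     !apply(ann$mask == "dropped", 1, any))
      if (length(eps) < 3) next
      H <- hjorth_array(rec, eps)
      drop_ep <- rep(FALSE, length(eps))
      for (ch in seq_len(n_ch)) {
        for (p in 1:3) {
          v <- H[, ch, p]
          if (anyNA(v)) next
          mu <- mean(v); s <- stats::sd(v)
          if (s > 0) drop_ep <- drop_ep | abs(v - mu) > cfg$per_channel_sd * s
        }
      }
      if (any(drop_ep)) ann$mask[eps[drop_ep], ] <- "dropped"
    }
  }
  list(rec = rec, ann = ann, bad_channels = all_bad)
}
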