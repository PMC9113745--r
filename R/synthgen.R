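#' Synthetic NREM EEG generation
#'
#' The generator builds N2-like multichannel EEG from three ingredients:
#' 1/f ("pink") background noise with a controllable spectral exponent,
#' biphasic slow-oscillation (SO) waveforms, and enveloped spindle bursts
#' with optional linear intra-event frequency ramps (chirp) and von-Mises
#' SO-phase coupling. Every injected event is recorded in a ground-truth
#' table so detector recall/precision and coupling recovery can be measured
#' exactly. All draws are reproducible under a fixed seed.
#'
#' @name synthgen
NULL

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Background-EEG specification
#'
#' @param n_channels number of channels.
#' @param duration seconds.
#' @param fs sampling rate, Hz (200 by default, the pipeline's working rate).
#' @param one_over_f_slope exponent s of the target power spectrum
#'   P(f) ~ f^(-s) over 0.5-35 Hz.
#' @param rms per-channel root-mean-square amplitude, microvolts.
#' @param seed integer RNG seed.
#' @return list of class `background_spec`.
#' @export
background_spec <- function(n_channels = 1, duration = 600, fs = 200,
                            one_over_f_slope = 2, rms = 20, seed = 1) {
  if (fs <= 0 || duration <= 0) stop("fs and duration must be positive")
  if (rms < 0) stop("rms must be >= 0")
  structure(list(n_channels = n_channels, duration = duration, fs = fs,
                 one_over_f_slope = one_over_f_slope, rms = rms, seed = seed),
            class = "background_spec")
}

#' Spindle specification
#'
#' @param center_freq Hz; 11 (slow) or 15 (fast) in this pipeline.
#' @param density events per minute of eligible sleep.
#' @param duration_mean event duration, seconds (0.3-3).
#' @param amplitude peak-to-peak microvolts at the envelope peak.
#' @param chirp Hz: implied frequency of the second half minus the first half
#'   (negative = deceleration). Realized as a linear instantaneous-frequency
#'   ramp from `center_freq - chirp` to `center_freq + chirp`, whose
#'   half-means differ by exactly `chirp`.
#' @param envelope "hann" or "gauss".
#' @param coupling_phase SO phase (degrees in `[0,360)`) at which the spindle
#'   envelope peak is placed, or NULL for uncoupled placement.
#' @param coupling_kappa von Mises concentration of the phase draw.
#' @return list of class `spindle_spec`.
#' @export
spindle_spec <- function(center_freq = 15, density = 2.7, duration_mean = 1,
                         amplitude = 30, chirp = -0.5, envelope = "hann",
                         coupling_phase = NULL, coupling_kappa = 5) {
  if (density < 0) stop("density must be >= 0")
  if (duration_mean <= 0.3 || duration_mean >= 3)
    stop("duration_mean must be in (0.3, 3) s")
  if (!is.null(coupling_phase) &&
      (coupling_phase < 0 || coupling_phase >= 360))
    stop("coupling_phase must be in [0, 360)")
  envelope <- match.arg(envelope, c("hann", "gauss"))
  structure(list(center_freq = center_freq, density = density,
                 duration_mean = duration_mean, amplitude = amplitude,
                 chirp = chirp, envelope = envelope,
                 coupling_phase = coupling_phase,
                 coupling_kappa = coupling_kappa),
            class = "spindle_spec")
}

#' Slow-oscillation specification
#'
#' Durations mirror the detector's temporal criteria (negative half-wave
#' 0.3-1.5 s, positive half-wave at most 1 s) so injected events are
#' detectable by construction.
#'
#' @param density events per minute.
#' @param neg_peak_amp negative-peak amplitude, microvolts (< 0).
#' @param pos_peak_amp positive-peak amplitude, microvolts (> 0).
#' @param neg_halfwave_dur,pos_halfwave_dur half-wave durations, seconds.
#' @return list of class `so_spec`.
#' @export
so_spec <- function(density = 5, neg_peak_amp = -60, pos_peak_amp = 40,
                    neg_halfwave_dur = 0.6, pos_halfwave_dur = 0.5) {
  if (neg_halfwave_dur < 0.3 || neg_halfwave_dur > 1.5)
    stop("neg_halfwave_dur must be in [0.3, 1.5] s")
  if (pos_halfwave_dur > 1.0) stop("pos_halfwave_dur must be <= 1 s")
  if (neg_peak_amp >= 0) stop("neg_peak_amp must be negative")
  structure(list(density = density, neg_peak_amp = neg_peak_amp,
                 pos_peak_amp = pos_peak_amp,
                 neg_halfwave_dur = neg_halfwave_dur,
                 pos_halfwave_dur = pos_halfwave_dur),
            class = "so_spec")
}

# roughly uniform unit-sphere positions on the upper hemisphere (used when a
# montage is needed but none supplied)
default_positions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # upper hemisphere: z in (0, 1)
  phi <- pi * (1 + sqrt(5)) * i    # golden-angle spiral
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Generate 1/f background EEG
#'
#' White Gaussian noise is spectrally shaped in the frequency domain so the
#' power spectrum falls as f^(-slope) above 0.5 Hz (flat below, zero DC),
#' then scaled to the requested rms. Channels are independent unless a
#' square `mixing` matrix is supplied.
#'
#' @param spec a [background_spec()].
#' @param mixing optional n_channels x n_channels mixing matrix applied to
#'   the independent channel signals.
#' @return a [new_recording()] object.
#' @export
make_background <- function(spec, mixing = NULL) {
  stopifnot(inherits(spec, "background_spec"))
  n <- round(spec$duration * spec$fs)
  if (n < 2) stop("duration too short")
  with_seed(spec$seed, {
    f <- seq(0, spec$fs - spec$fs / n, length.out = n)
    f <- pmin(f, spec$fs - f)                   # two-sided frequency axis
    shape <- pmax(f, 0.5)^(-spec$one_over_f_slope / 2)
    shape[f == 0] <- 0
    dat <- matrix(0, spec$n_channels, n)
    for (ch in seq_len(spec$n_channels)) {
      w <- stats::rnorm(n)
      x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n
      s <- stats::sd(x)
      dat[ch, ] <- if (s > 0 && spec$rms > 0) x * (spec$rms / s) else x * 0
    }
    if (!is.null(mixing)) {
      stopifnot(nrow(mixing) == spec$n_channels,
                ncol(mixing) == spec$n_channels)
      dat <- mixing %*% dat
    }
    new_recording(dat, spec$fs,
                  positions = default_positions(spec$n_channels))
  })
}

# analytic SO waveform: negative half-sine then positive half-sine
so_waveform <- function(spec, fs) {
  n1 <- round(spec$neg_halfwave_dur * fs)
  n2 <- round(spec$pos_halfwave_dur * fs)
  c(spec$neg_peak_amp * sin(pi * seq_len(n1) / (n1 + 1)),
    spec$pos_peak_amp * sin(pi * seq_len(n2) / (n2 + 1)))
}

# spindle waveform with linear instantaneous-frequency ramp fc-c ... fc+c
spindle_waveform <- function(spec, fs) {
  n <- round(spec$duration_mean * fs)
  t01 <- (seq_len(n) - 0.5) / n
  finst <- spec$center_freq + spec$chirp * (2 * t01 - 1)
  phase <- 2 * pi * cumsum(finst) / fs
  env <- switch(spec$envelope,
                hann = 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))),
                gauss = exp(-((seq_len(n) - (n + 1) / 2)^2) /
                              (2 * (n / 6)^2)))
  (spec$amplitude / 2) * env * sin(phase)
}

# sample positions (starts) for `k` non-overlapping events of length `len`
# inside allowed sample runs; NULL mask = whole signal. Events must fit in a
# single run (and so never straddle epoch/stage boundaries when the mask
# encodes them).
place_events <- function(k, len, n_total, allowed = NULL, occupied = NULL,
                         gap = 0L, max_tries = 2000L) {
  if (is.null(allowed)) allowed <- rep(TRUE, n_total)
  runs <- true_runs(allowed)
  runs <- runs[runs[, 2] - runs[, 1] + 1L >= len, , drop = FALSE]
  if (k > 0 && nrow(runs) == 0) stop("no room to place events")
  starts <- integer(0)
  occ <- occupied
  for (i in seq_len(k)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r <- runs[sample.int(nrow(runs), 1), ]
      s <- r[1] + sample.int(r[2] - r[1] - len + 2L, 1) - 1L
      iv <- c(s - gap, s + len - 1L + gap)
      clash <- FALSE
      if (length(starts))
        clash <- any(starts <= iv[2] & (starts + len - 1L) >= iv[1])
      if (!clash && !is.null(occ))
        clash <- any(occ[, 1] <= iv[2] & occ[, 2] >= iv[1])
      if (!clash) { starts <- c(starts, s); placed <- TRUE; break }
    }
    if (!placed) stop("event density too high: cannot place non-overlapping events")
  }
  sort(starts)
}

#' Inject slow oscillations into a recording
#'
#' Biphasic waveforms (negative then positive half-sine) are added at
#' randomly placed, non-overlapping onsets. The event count is a Poisson
#' draw at `spec$density` per minute of eligible signal unless `n_events`
#' fixes it exactly.
#'
#' @param rec a recording.
#' @param spec an [so_spec()].
#' @param seed RNG seed.
#' @param channels channel indices to inject into (independent draws each).
#' @param allowed_mask optional per-sample logical mask of eligible samples.
#' @param n_events exact event count per channel, or NULL for Poisson.
#' @return list with elements `rec` (recording with events added) and
#'   `truth` (data.frame: channel, start, end, neg_peak samples, onset_s,
#'   neg_peak_s, amplitudes).
#' @export
inject_so <- function(rec, spec, seed = 1, channels = seq_len(nrow(rec$data)),
                      allowed_mask = NULL, n_events = NULL, min_gap = 1.25) {
  stopifnot(inherits(spec, "so_spec"))
  wf <- so_waveform(spec, rec$fs)
  len <- length(wf)
  n1 <- round(spec$neg_halfwave_dur * rec$fs)
  nt <- n_samples(rec)
  minutes <- if (is.null(allowed_mask)) nt / rec$fs / 60 else
    sum(allowed_mask) / rec$fs / 60
  truth <- list()
  with_seed(seed, {
    for (ch in channels) {
      k <- if (is.null(n_events)) stats::rpois(1, spec$density * minutes)
      else n_events
      if (k == 0) next
      starts <- place_events(k, len, nt, allowed_mask,
                             gap = round(min_gap * rec$fs))
      for (s in starts) rec$data[ch, s:(s + len - 1L)] <-
        rec$data[ch, s:(s + len - 1L)] + wf
      neg_peak <- starts + which.min(wf[seq_len(n1)]) - 1L
      truth[[length(truth) + 1L]] <- data.frame(
        channel = ch, start = starts, end = starts + len - 1L,
        neg_peak = neg_peak, onset_s = (starts - 1) / rec$fs,
        neg_peak_s = (neg_peak - 1) / rec$fs,
        neg_peak_amp = spec$neg_peak_amp,
        p2p_amp = spec$pos_peak_amp - spec$neg_peak_amp,
        duration = len / rec$fs)
    }
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(channel = integer(0), start = integer(0), end = integer(0),
               neg_peak = integer(0), onset_s = numeric(0),
               neg_peak_s = numeric(0), neg_peak_amp = numeric(0),
               p2p_amp = numeric(0), duration = numeric(0))
  list(rec = rec, truth = truth)
}

# Best-Fisher (1979) von Mises sampler; mu in radians
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

circ_dist_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Inject spindles into a recording
#'
#' Each spindle is an enveloped sinusoid with a linear
#' instantaneous-frequency ramp realizing the requested chirp. With
#' `spec$coupling_phase` set, the envelope peak of each spindle is placed at
#' the sample where the concurrent SO's analytic phase equals a von-Mises
#' draw around that phase; `so_truth` must then be supplied (the phase is
#' evaluated on the clean reconstructed SO waveform so ground truth is exact).
#'
#' @param rec a recording.
#' @param spec a [spindle_spec()].
#' @param so_truth SO ground-truth table from [inject_so()] (required for
#'   coupled placement) together with its `so_spec` via attribute, or NULL.
#' @param so_spec_used the [so_spec()] used to generate `so_truth`
#'   (needed to reconstruct the clean SO waveform for phase lookup).
#' @param seed RNG seed.
#' @param channels channel indices.
#' @param allowed_mask per-sample eligibility mask.
#' @param n_events exact per-channel count, or NULL for a Poisson draw.
#' @return list with `rec` and `truth` (channel, start, end, peak samples,
#'   peak_s, center_freq, chirp, duration, target_phase).
#' @export
inject_spindles <- function(rec, spec, so_truth = NULL, so_spec_used = NULL,
                            seed = 1, channels = seq_len(nrow(rec$data)),
                            allowed_mask = NULL, n_events = NULL) {
  stopifnot(inherits(spec, "spindle_spec"))
  coupled <- !is.null(spec$coupling_phase)
  if (coupled && (is.null(so_truth) || nrow(so_truth) == 0))
    stop("coupled placement requested but SO truth is empty")
  if (coupled && is.null(so_spec_used))
    stop("coupled placement needs the so_spec used for injection")
  wf <- spindle_waveform(spec, rec$fs)
  len <- length(wf)
  peak_off <- which.max(abs(spindle_envelope_only(spec, rec$fs))) - 1L
  nt <- n_samples(rec)
  minutes <- if (is.null(allowed_mask)) nt / rec$fs / 60 else
    sum(allowed_mask) / rec$fs / 60
  truth <- list()
  with_seed(seed, {
    for (ch in channels) {
      k <- if (is.null(n_events)) stats::rpois(1, spec$density * minutes)
      else n_events
      if (k == 0) next
      if (!coupled) {
        starts <- place_events(k, len, nt, allowed_mask)
        target_phase <- rep(NA_real_, k)
      } else {
        st <- so_truth[so_truth$channel == ch, , drop = FALSE]
        if (nrow(st) == 0) stop("no SO truth events on channel ", ch)
        # clean SO signal -> exact phase series
        clean <- numeric(nt)
        sowf <- so_waveform(so_spec_used, rec$fs)
        for (j in seq_len(nrow(st)))
          clean[st$start[j]:st$end[j]] <- sowf
        ph <- inst_phase_deg(bp_filter(clean, rec$fs, 0.5, 4))
        idx <- if (nrow(st) >= k) sample(seq_len(nrow(st)), k)
        else sample(seq_len(nrow(st)), k, replace = TRUE)
        draw <- rvonmises(k, spec$coupling_phase * pi / 180,
                          spec$coupling_kappa) * 180 / pi
        peaks <- integer(k)
        for (j in seq_len(k)) {
          span <- st$start[idx[j]]:st$end[idx[j]]
          peaks[j] <- span[which.min(circ_dist_deg(ph[span], draw[j]))]
        }
        starts <- pmax(pmin(peaks - peak_off, nt - len + 1L), 1L)
        target_phase <- draw
        o <- order(starts); starts <- starts[o]; target_phase <- target_phase[o]
      }
      for (s in starts) rec$data[ch, s:(s + len - 1L)] <-
        rec$data[ch, s:(s + len - 1L)] + wf
      truth[[length(truth) + 1L]] <- data.frame(
        channel = ch, start = starts, end = starts + len - 1L,
        peak = starts + peak_off,
        peak_s = (starts + peak_off - 1) / rec$fs,
        center_freq = spec$center_freq, chirp = spec$chirp,
        duration = len / rec$fs, target_phase = target_phase)
    }
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(channel = integer(0), start = integer(0), end = integer(0),
               peak = integer(0), peak_s = numeric(0),
               center_freq = numeric(0), chirp = numeric(0),
               duration = numeric(0), target_phase = numeric(0))
  list(rec = rec, truth = truth)
}

spindle_envelope_only <- function(spec, fs) {
  n <- round(spec$duration_mean * fs)
  switch(spec$envelope,
         hann = 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1))),
         gauss = exp(-((seq_len(n) - (n + 1) / 2)^2) / (2 * (n / 6)^2)))
}

#' Simulate one subject's N2 recording with ground truth
#'
#' Builds background EEG, labels a contiguous block of 30-s epochs as N2
#' (the rest "W"), and injects SOs, slow and fast spindles only inside N2
#' epochs, never straddling an epoch boundary. Event counts are exact:
#' `round(density * N2 minutes)` per channel, so the true density is fixed
#' by construction.
#'
#' @param background a [background_spec()].
#' @param so an [so_spec()] or NULL.
#' @param slow,fast [spindle_spec()]s or NULL.
#' @param n2_fraction fraction of epochs labeled N2 (contiguous from start).
#' @param seed RNG seed.
#' @return list: `rec`, `stages` ([new_stage_annotation()]),
#'   `truth` (list with `so`, `slow`, `fast` tables).
#' @export
simulate_subject <- function(background, so = so_spec(),
                             slow = spindle_spec(center_freq = 11, density = 2),
                             fast = spindle_spec(center_freq = 15, density = 2.7),
                             n2_fraction = 0.85, seed = 1) {
  if (n2_fraction <= 0 || n2_fraction > 1) stop("n2_fraction must be in (0,1]")
  n_ep <- floor(background$duration / 30)
  if (n_ep < 1) stop("duration shorter than one 30-s epoch")
  background$duration <- n_ep * 30
  background$seed <- seed
  rec <- make_background(background)
  n2_ep <- max(1L, round(n2_fraction * n_ep))
  stages <- c(rep("N2", n2_ep), rep("W", n_ep - n2_ep))
  ann <- new_stage_annotation(stages, 30, n_channels = nrow(rec$data))
  # eligibility mask: N2 samples, with epoch boundaries enforced by marking
  # each epoch a separate run (drop last sample of each epoch from the mask
  # is unnecessary: place_events requires the event to fit within one run,
  # and runs are split at epoch boundaries below)
  fs <- rec$fs
  nt <- n_samples(rec)
  mask <- stage_sample_mask(ann, fs, nt, "N2")
  # split runs at epoch boundaries so no event straddles one
  spe <- round(30 * fs)
  bnd <- seq(spe, nt, by = spe)
  mask[bnd] <- FALSE
  minutes <- sum(stages == "N2") * 30 / 60
  truth <- list()
  cur <- rec
  if (!is.null(so)) {
    out <- inject_so(cur, so, seed = seed + 1L, allowed_mask = mask,
                     n_events = round(so$density * minutes))
    cur <- out$rec; truth$so <- out$truth
  }
  if (!is.null(slow)) {
    out <- inject_spindles(cur, slow, so_truth = truth$so, so_spec_used = so,
                           seed = seed + 2L, allowed_mask = mask,
                           n_events = round(slow$density * minutes))
    cur <- out$rec; truth$slow <- out$truth
  }
  if (!is.null(fast)) {
    out <- inject_spindles(cur, fast, so_truth = truth$so, so_spec_used = so,
                           seed = seed + 3L, allowed_mask = mask,
                           n_events = round(fast$density * minutes))
    cur <- out$rec; truth$fast <- out$truth
  }
  list(rec = cur, stages = ann, truth = truth, n2_minutes = minutes)
}

#' Cohort specification
#'
#' @param n_cases,n_controls group sizes.
#' @param effect_sizes named numeric vector: standardized (SD-unit) group
#'   differences, case minus control, per metric.
#' @param age_mean_case,age_mean_control,age_sd age distributions, years.
#' @param sex_ratio fraction female.
#' @param seed RNG seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, effect_sizes = c(metric1 = 0),
                        age_mean_case = 34.8, age_mean_control = 31.7,
                        age_sd = 6.7, sex_ratio = 0.4, seed = 1) {
  if (n_cases <= 0 || n_controls <= 0) stop("group sizes must be positive")
  if (is.null(names(effect_sizes)) || any(names(effect_sizes) == ""))
    stop("effect_sizes must be a named vector")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 effect_sizes = effect_sizes,
                 age_mean_case = age_mean_case,
                 age_mean_control = age_mean_control, age_sd = age_sd,
                 sex_ratio = sex_ratio, seed = seed),
            class = "cohort_spec")
}

#' Simulate a case/control cohort of metric values
#'
#' Metric mode of the cohort generator: draws subject x channel metric
#' values as standard-normal variates with an equicorrelated channel
#' structure (correlation `channel_rho`), adds the requested standardized
#' case/control difference per metric, an optional linear age slope (SD
#' units per SD of age), and age/sex covariates.
#'
#' @param spec a [cohort_spec()].
#' @param n_channels channels per metric.
#' @param channel_rho common inter-channel correlation.
#' @param age_slopes optional named vector of age slopes per metric.
#' @return list: `metrics` (named list of subject x channel matrices),
#'   `covariates` (data.frame: group, age, sex).
#' @export
simulate_cohort_metrics <- function(spec, n_channels = 1, channel_rho = 0.5,
                                    age_slopes = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(age_slopes) &&
      !all(names(age_slopes) %in% names(spec$effect_sizes)))
    stop("unknown metric name in age_slopes")
  n <- spec$n_cases + spec$n_controls
  with_seed(spec$seed, {
    group <- factor(c(rep("case", spec$n_cases),
                      rep("control", spec$n_controls)),
                    levels = c("control", "case"))
    age <- c(stats::rnorm(spec$n_cases, spec$age_mean_case, spec$age_sd),
             stats::rnorm(spec$n_controls, spec$age_mean_control, spec$age_sd))
    sex <- factor(ifelse(stats::runif(n) < spec$sex_ratio, "F", "M"),
                  levels = c("M", "F"))
    metrics <- list()
    for (m in names(spec$effect_sizes)) {
      shared <- stats::rnorm(n)
      eps <- matrix(stats::rnorm(n * n_channels), n, n_channels)
      vals <- sqrt(channel_rho) * shared + sqrt(1 - channel_rho) * eps
      vals <- vals + spec$effect_sizes[[m]] * (group == "case")
      if (!is.null(age_slopes) && m %in% names(age_slopes))
        vals <- vals + age_slopes[[m]] * scale(age)[, 1]
      colnames(vals) <- paste0("CH", seq_len(n_channels))
      metrics[[m]] <- vals
    }
    list(metrics = metrics,
         covariates = data.frame(group = group, age = age, sex = sex))
  })
}

#' Simulate a cohort of full recordings
#'
#' Signal mode of the cohort generator: each subject gets an independent
#' [simulate_subject()] draw; cases may use modified template specs
#' (e.g. reduced spindle density).
#'
#' @param spec a [cohort_spec()] (effect_sizes ignored in this mode).
#' @param template named list of control templates: background, so, slow,
#'   fast, n2_fraction.
#' @param template_case overrides for cases (same structure; NULL = same).
#' @return list: `subjects` (list of simulate_subject outputs),
#'   `covariates` data.frame.
#' @export
simulate_cohort_signals <- function(spec, template, template_case = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_cases + spec$n_controls
  covs <- with_seed(spec$seed, {
    group <- factor(c(rep("case", spec$n_cases),
                      rep("control", spec$n_controls)),
                    levels = c("control", "case"))
    age <- c(stats::rnorm(spec$n_cases, spec$age_mean_case, spec$age_sd),
             stats::rnorm(spec$n_controls, spec$age_mean_control, spec$age_sd))
    sex <- factor(ifelse(stats::runif(n) < spec$sex_ratio, "F", "M"),
                  levels = c("M", "F"))
    data.frame(group = group, age = age, sex = sex)
  })
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    tpl <- if (covs$group[i] == "case" && !is.null(template_case))
      utils::modifyList(template, template_case) else template
    subjects[[i]] <- simulate_subject(
      background = tpl$background, so = tpl$so, slow = tpl$slow,
      fast = tpl$fast,
      n2_fraction = if (is.null(tpl$n2_fraction)) 0.85 else tpl$n2_fraction,
      seed = (spec$seed %% 1000000L) * 1000L + i)
  }
  list(subjects = subjects, covariates = covs)
}
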