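#' Slow-oscillation phase series
#'
#' Filter-Hilbert phase of the 0.5-4 Hz filtered signal, in degrees with
#' the convention: 0 = SO positive peak, 180 = negative peak, 180-270 =
#' rising slope.
#'
#' @param x preprocessed signal.
#' @param fs sampling rate, Hz.
#' @param band SO band, Hz.
#' @return per-sample phase in `[0, 360)` degrees.
#' @export
so_phase <- function(x, fs, band = c(0.5, 4)) {
  inst_phase_deg(bp_filter(x, fs, band[1], band[2]))
}

#' Raw SO/spindle coupling metrics
#'
#' Overlap: proportion of spindles whose `[start, end]` intersects any SO
#' interval. Magnitude: inter-trial phase clustering (length of the mean
#' unit phasor) of the SO phase at the spindle peaks. Mean angle: argument
#' of that mean phasor.
#'
#' @param spindles spindle events (needs `start`, `end`, and `peak` sample
#'   columns; [detect_spindles()] output works after adding `peak` =
#'   `round(peak_time * fs) + 1`, see [spindle_peak_samples()]).
#' @param so SO events (needs `start`, `end`).
#' @param phase per-sample SO phase in degrees from [so_phase()].
#' @return list: overlap_raw, magnitude_raw, mean_angle (degrees), n.
#' @export
coupling_metrics <- function(spindles, so, phase) {
  n <- nrow(spindles)
  if (n == 0)
    return(list(overlap_raw = NA_real_, magnitude_raw = NA_real_,
                mean_angle = NA_real_, n = 0L))
  overl <- vapply(seq_len(n), function(i)
    any(so$start <= spindles$end[i] & so$end >= spindles$start[i]), TRUE)
  th <- phase[spindles$peak] * pi / 180
  z <- mean(exp(1i * th))
  list(overlap_raw = mean(overl), magnitude_raw = Mod(z),
       mean_angle = (Arg(z) * 180 / pi) %% 360, n = n)
}

#' Peak sample indices for detected spindle events
#'
#' @param events [detect_spindles()] output.
#' @param fs sampling rate.
#' @return `events` with an integer `peak` column added.
#' @export
spindle_peak_samples <- function(events, fs) {
  events$peak <- round(events$peak_time * fs) + 1L
  events
}

#' Surrogate-normalized coupling Z-scores
#'
#' Overlap null: each spindle is relocated (duration preserved) uniformly
#' within the clean in-stage samples. Magnitude null: each spindle peak is
#' relocated uniformly within the union of SO intervals, preserving gross
#' overlap. Z = (observed - null mean) / null SD; the per-subject empirical
#' p-value is `(r + 1) / (n_shuffles + 1)` with `r` the number of null
#' statistics at or above the observed one.
#'
#' @param raw list from [coupling_metrics()].
#' @param spindles,so event tables (with `peak` for spindles).
#' @param phase SO phase series, degrees.
#' @param mask clean in-stage sample mask.
#' @param n_shuffles surrogate count (10000 in the full pipeline).
#' @param seed RNG seed.
#' @param which which nulls to compute ("both", "magnitude", "overlap");
#'   the magnitude-only path is vectorized and much faster.
#' @return `raw` extended with overlap_z, magnitude_z, overlap_p,
#'   magnitude_p.
#' @export
surrogate_normalize <- function(raw, spindles, so, phase, mask,
                                n_shuffles = 10000, seed = 1,
                                which = c("both", "magnitude", "overlap")) {
  which <- match.arg(which)
  n <- nrow(spindles)
  if (n == 0 || nrow(so) == 0) {
    raw$overlap_z <- raw$magnitude_z <- NA_real_
    raw$overlap_p <- raw$magnitude_p <- NA_real_
    return(raw)
  }
  durs <- spindles$end - spindles$start + 1L
  so_samples <- unlist(lapply(seq_len(nrow(so)), function(i)
    so$start[i]:so$end[i]))
  clean_idx <- which(mask)
  null_ov <- null_mag <- NULL
  with_seed(seed, {
    if (which != "magnitude") {
      # overlap null: uniform relocation of whole events within clean samples
      null_ov <- numeric(n_shuffles)
      so_start <- so$start; so_end <- so$end
      for (r in seq_len(n_shuffles)) {
        starts <- clean_idx[sample.int(length(clean_idx), n, replace = TRUE)]
        ends <- starts + durs - 1L
        hit <- vapply(seq_len(n), function(i)
          any(so_start <= ends[i] & so_end >= starts[i]), TRUE)
        null_ov[r] <- mean(hit)
      }
    }
    if (which != "overlap") {
      # magnitude null: peaks uniform within the union of SO intervals
      th_null <- matrix(phase[so_samples[sample.int(length(so_samples),
                                                    n * n_shuffles,
                                                    replace = TRUE)]] * pi / 180,
                        nrow = n_shuffles)
      null_mag <- Mod(rowMeans(exp(1i * th_null)))
    }
  })
  zp <- function(obs, null) {
    s <- stats::sd(null)
    z <- if (s > 0) (obs - mean(null)) / s else NA_real_
    p <- (sum(null >= obs) + 1) / (length(null) + 1)
    c(z, p)
  }
  if (!is.null(null_ov)) {
    ov <- zp(raw$overlap_raw, null_ov)
    raw$overlap_z <- ov[1]; raw$overlap_p <- ov[2]
  }
  if (!is.null(null_mag)) {
    mg <- zp(raw$magnitude_raw, null_mag)
    raw$magnitude_z <- mg[1]; raw$magnitude_p <- mg[2]
  }
  raw
}

#' Instantaneous spindle frequency
#'
#' Filter-Hilbert estimate: the signal is bandpassed `mean_freq` +/- 2 Hz,
#' the unwrapped analytic phase differentiated and smoothed over 3 samples.
#'
#' @param x signal (whole trace or an event window with margins).
#' @param fs sampling rate.
#' @param mean_freq per-subject/channel mean observed spindle frequency, Hz.
#' @return per-sample frequency, Hz (same length; endpoint replicated).
#' @export
instantaneous_frequency <- function(x, fs, mean_freq) {
  xf <- bp_filter(x, fs, mean_freq - 2, mean_freq + 2)
  ph <- Arg(analytic_signal(xf))
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi   # unwrap increments
  f <- dph * fs / (2 * pi)
  f <- c(f, f[length(f)])
  moving_average(f, 3)
}

#' Phase/frequency modulation profiles
#'
#' Summarizes per-sample instantaneous spindle frequency by spindle
#' progression quintile (five equal-time fifths of each event), by SO phase
#' (eighteen 20-degree bins), and jointly (5 x 18), averaging across
#' events. Also reports the Mardia circular-linear correlation between the
#' 18 bin centers and bin mean frequencies.
#'
#' @param events spindle events (needs `start`, `end`).
#' @param freq per-sample instantaneous frequency, Hz.
#' @param phase per-sample SO phase, degrees.
#' @return list: freq_by_quintile (5), freq_by_phase_bin (18),
#'   joint (5 x 18), circ_lin_r, n_events.
#' @export
phase_freq_profiles <- function(events, freq, phase) {
  n <- nrow(events)
  if (n == 0) stop("no events")
  qsum <- matrix(0, n, 5)
  bsum <- array(NA_real_, c(n, 18))
  jsum <- array(NA_real_, c(n, 5, 18))
  for (i in seq_len(n)) {
    idx <- events$start[i]:events$end[i]
    f <- freq[idx]
    quint <- pmin(floor(5 * (seq_along(idx) - 1) / length(idx)) + 1, 5)
    bin <- pmin(floor(phase[idx] / 20) + 1, 18)
    qsum[i, ] <- tapply(f, factor(quint, levels = 1:5), mean)
    bsum[i, ] <- tapply(f, factor(bin, levels = 1:18), mean)
    jsum[i, , ] <- tapply(f, list(factor(quint, levels = 1:5),
                                  factor(bin, levels = 1:18)), mean)
  }
  fq <- colMeans(qsum, na.rm = TRUE)
  fb <- colMeans(bsum, na.rm = TRUE)
  jm <- apply(jsum, c(2, 3), mean, na.rm = TRUE)
  centers <- seq(10, 350, by = 20)
  r <- circ_linear_corr(centers, fb)
  list(freq_by_quintile = fq, freq_by_phase_bin = fb, joint = jm,
       circ_lin_r = r, n_events = n)
}

#' Mardia circular-linear correlation
#'
#' \deqn{r = \sqrt{(r_{xc}^2 + r_{xs}^2 - 2 r_{xc} r_{xs} r_{cs}) /
#' (1 - r_{cs}^2)}}
#' with \eqn{r_{xc}} the correlation of v with cos(theta), \eqn{r_{xs}}
#' with sin(theta), and \eqn{r_{cs}} that of cos(theta) with sin(theta).
#' Missing bins are dropped; constant
#' values give 0.
#'
#' @param theta_deg angles in degrees.
#' @param v linear values (same length).
#' @return correlation in `[0, 1]`.
#' @export
circ_linear_corr <- function(theta_deg, v) {
  ok <- is.finite(theta_deg) & is.finite(v)
  theta <- theta_deg[ok] * pi / 180
  v <- v[ok]
  if (length(v) < 3) stop("need at least 3 non-missing bins")
  if (stats::sd(v) == 0) return(0)
  cs <- cos(theta); sn <- sin(theta)
  rxc <- stats::cor(v, cs); rxs <- stats::cor(v, sn)
  rcs <- stats::cor(cs, sn)
  r2 <- (rxc^2 + rxs^2 - 2 * rxc * rxs * rcs) / (1 - rcs^2)
  sqrt(pmin(pmax(r2, 0), 1))
}

#' Cubic progression / circular-harmonic models of spindle frequency
#'
#' Least-squares fits to the 5 x 18 binned mean-frequency matrix:
#' progression-only (cubic polynomial in quintile index), phase-only
#' (sin/cos harmonics k = 1..3 of SO phase) and the additive combination,
#' each reported as adjusted R^2.
#'
#' @param joint 5 x 18 matrix of binned mean frequencies (NA cells dropped).
#' @return named numeric: progression, phase, combined (adjusted R^2).
#' @export
fit_freq_model <- function(joint) {
  stopifnot(is.matrix(joint), nrow(joint) == 5, ncol(joint) == 18)
  grid <- expand.grid(q = 1:5, b = 1:18)
  y <- joint[cbind(grid$q, grid$b)]
  ok <- is.finite(y)
  grid <- grid[ok, ]; y <- y[ok]
  q <- scale(grid$q, scale = FALSE)[, 1]
  th <- (grid$b - 0.5) * 20 * pi / 180
  prog <- cbind(q, q^2, q^3)
  harm <- do.call(cbind, lapply(1:3, function(k) cbind(sin(k * th),
                                                       cos(k * th))))
  adj_r2 <- function(X) {
    fit <- stats::lm.fit(cbind(1, X), y)
    if (fit$rank < ncol(X) + 1) stop("rank-deficient design")
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    n <- length(y); p <- ncol(X)
    1 - (rss / (n - p - 1)) / (tss / (n - 1))
  }
  c(progression = adj_r2(prog), phase = adj_r2(harm),
    combined = adj_r2(cbind(prog, harm)))
}
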