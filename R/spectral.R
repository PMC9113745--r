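#' Tukey (tapered cosine) window
#'
#' @param n window length in samples.
#' @param r taper fraction (0 = rectangular, 1 = Hann); 0.5 by default.
#' @return numeric window of length `n`.
#' @export
tukey_window <- function(n, r = 0.5) {
  if (r <= 0) return(rep(1, n))
  if (r >= 1) return(0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1))))
  t <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- t < r / 2
  hi <- t > 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / r - 2 / r + 1)))
  w
}

# one-sided PSD (uV^2/Hz) of tapered segments; rows = segments
segment_psds <- function(x, fs, starts, seg, taper) {
  nf <- seg %/% 2 + 1
  out <- matrix(0, length(starts), nf)
  scale <- 1 / (fs * sum(taper^2))
  for (k in seq_along(starts)) {
    X <- stats::fft(x[starts[k]:(starts[k] + seg - 1)] * taper)
    p <- Mod(X[seq_len(nf)])^2 * scale
    last <- if (seg %% 2 == 0) nf - 1 else nf
    p[2:last] <- 2 * p[2:last]
    out[k, ] <- p
  }
  out
}

#' Welch power spectral density
#'
#' Standard sleep-EEG segmentation: within each 30-s epoch, 4-s segments
#' with 50% overlap and a Tukey(0.5) taper, power averaged across segments
#' per epoch, then across epochs. 0.25 Hz resolution.
#'
#' @param x one channel's signal, microvolts.
#' @param fs sampling rate, Hz.
#' @param mask logical mask of clean in-stage samples; only epochs fully
#'   inside it are used (NULL = use everything).
#' @param epoch_len epoch length, seconds.
#' @param seg_len segment length, seconds.
#' @param overlap segment overlap fraction.
#' @param fmin,fmax returned frequency range, Hz.
#' @return list: `freq` (Hz), `power` (uV^2/Hz), `log_power` (10*log10),
#'   `n_epochs`.
#' @export
welch_psd <- function(x, fs, mask = NULL, epoch_len = 30, seg_len = 4,
                      overlap = 0.5, fmin = 0.5, fmax = 20) {
  n <- length(x)
  if (is.null(mask)) mask <- rep(TRUE, n)
  seg <- round(seg_len * fs)
  if (n < seg) stop("signal shorter than one segment")
  spe <- round(epoch_len * fs)
  step <- max(1, round(seg * (1 - overlap)))
  taper <- tukey_window(seg, 0.5)
  ep_starts <- seq(1, n - spe + 1, by = spe)
  if (length(ep_starts) == 0) ep_starts <- 1
  acc <- NULL
  n_ep <- 0
  for (e0 in ep_starts) {
    e1 <- min(e0 + spe - 1, n)
    if (!all(mask[e0:e1])) next
    starts <- seq(e0, e1 - seg + 1, by = step)
    psd_e <- colMeans(segment_psds(x, fs, starts, seg, taper))
    acc <- if (is.null(acc)) psd_e else acc + psd_e
    n_ep <- n_ep + 1
  }
  if (n_ep == 0) stop("no clean epochs to analyze")
  p <- acc / n_ep
  f <- (seq_along(p) - 1) * fs / seg
  sel <- f >= fmin & f <= fmax
  list(freq = f[sel], power = p[sel], log_power = 10 * log10(p[sel]),
       n_epochs = n_ep)
}

#' Band power from a PSD
#'
#' Sum of bin powers times the bin width over `[lo, hi]`.
#'
#' @param psd result of [welch_psd()].
#' @param band numeric(2): band edges, Hz.
#' @return power in uV^2.
#' @export
band_power <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  df <- psd$freq[2] - psd$freq[1]
  sum(psd$power[sel]) * df
}

#' Aperiodic (1/f) spectral slope
#'
#' Least-squares slope of log10 power on log10 frequency over the PSD's
#' frequency range (0.5-20 Hz by default upstream). A signal with power
#' ~ f^(-s) yields slope -s.
#'
#' @param psd result of [welch_psd()].
#' @return dimensionless slope.
#' @export
spectral_slope <- function(psd) {
  ok <- psd$power > 0
  if (sum(ok) < 2) stop("need at least two positive-power bins")
  stats::coef(stats::lm(log10(psd$power[ok]) ~ log10(psd$freq[ok])))[[2]]
}

#' Magnitude-squared coherence in a band
#'
#' Welch cross-spectral estimate `|S_xy|^2 / (S_xx S_yy)` averaged over the
#' band's bins, using the same 4-s/50%/Tukey(0.5) segmentation as
#' [welch_psd()] pooled over all segments.
#'
#' @param x,y equal-length signals at the same rate.
#' @param fs sampling rate, Hz.
#' @param band numeric(2), Hz.
#' @param seg_len,overlap segmentation parameters.
#' @return coherence in `[0, 1]`.
#' @export
ms_coherence <- function(x, y, fs, band = c(11, 15), seg_len = 4,
                         overlap = 0.5) {
  stopifnot(length(x) == length(y))
  seg <- round(seg_len * fs)
  step <- max(1, round(seg * (1 - overlap)))
  starts <- seq(1, length(x) - seg + 1, by = step)
  taper <- tukey_window(seg, 0.5)
  nf <- seg %/% 2 + 1
  sxx <- syy <- numeric(nf)
  sxy <- complex(nf)
  for (s in starts) {
    X <- stats::fft(x[s:(s + seg - 1)] * taper)[seq_len(nf)]
    Y <- stats::fft(y[s:(s + seg - 1)] * taper)[seq_len(nf)]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  f <- (seq_len(nf) - 1) * fs / seg
  sel <- f >= band[1] & f <= band[2]
  coh <- Mod(sxy[sel])^2 / (sxx[sel] * syy[sel])
  mean(coh)
}

#' Phase-slope-index configuration
#'
#' @param fcs center frequencies, Hz.
#' @param half_window half of the 5 Hz PSI integration window, Hz.
#' @param seg_len 4-s segments per epoch (non-overlapping).
#' @param sub_len 2-s sub-segments within each segment.
#' @param sub_overlap sub-segment overlap fraction.
#' @param epoch_len epoch length, seconds.
#' @param n_epochs number of randomly selected clean epochs.
#' @param seed RNG seed for epoch selection.
#' @return list of class `psi_config`.
#' @export
psi_config <- function(fcs = 3:20, half_window = 2.5, seg_len = 4,
                       sub_len = 2, sub_overlap = 0.5, epoch_len = 30,
                       n_epochs = 20, seed = 1) {
  structure(list(fcs = fcs, half_window = half_window, seg_len = seg_len,
                 sub_len = sub_len, sub_overlap = sub_overlap,
                 epoch_len = epoch_len, n_epochs = n_epochs, seed = seed),
            class = "psi_config")
}

# sub-segment start indices for one epoch [e0, e1]
psi_sub_starts <- function(e0, e1, fs, cfg) {
  seg <- round(cfg$seg_len * fs)
  sub <- round(cfg$sub_len * fs)
  sub_step <- max(1, round(sub * (1 - cfg$sub_overlap)))
  seg_starts <- seq(e0, e1 - seg + 1, by = seg)
  unlist(lapply(seg_starts, function(s0)
    seq(s0, s0 + seg - sub, by = sub_step)))
}

# complex sub-segment spectra: m x nf matrix (Hann taper)
psi_sub_ffts <- function(x, fs, starts, sub) {
  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(sub) - 1) / (sub - 1)))
  nf <- sub %/% 2 + 1
  out <- matrix(0i, length(starts), nf)
  for (k in seq_along(starts))
    out[k, ] <- stats::fft(x[starts[k]:(starts[k] + sub - 1)] * taper)[seq_len(nf)]
  out
}

# PSI per center frequency from cross-spectral sums over a sub-segment set
psi_from_spectra <- function(Fx, Fy, rows, f, fcs, half_window, df) {
  sxy <- colMeans(Fx[rows, , drop = FALSE] * Conj(Fy[rows, , drop = FALSE]))
  sxx <- colMeans(Mod(Fx[rows, , drop = FALSE])^2)
  syy <- colMeans(Mod(Fy[rows, , drop = FALSE])^2)
  C <- sxy / sqrt(sxx * syy)
  vapply(fcs, function(fc) {
    sel <- which(f >= fc - half_window & f + df <= fc + half_window + 1e-9)
    sel <- sel[sel + 1 <= length(C)]
    sum(Im(Conj(C[sel]) * C[sel + 1]))
  }, 0)
}

#' Phase slope index between two signals
#'
#' Nolte's PSI: the imaginary part of the frequency-derivative of complex
#' coherency, summed over a 5 Hz window around each center frequency
#' (3-20 Hz, 1 Hz steps). Coherency is estimated per 30-s epoch from 2-s
#' Hann sub-segments (50% overlap) of non-overlapping 4-s segments; each
#' epoch's PSI is normalized by its jackknife (leave-one-sub-segment-out)
#' SD and the normalized values averaged across epochs. Positive values
#' mean `x` leads `y`.
#'
#' @param x,y equal-length signals.
#' @param fs sampling rate, Hz.
#' @param cfg a [psi_config()].
#' @param epochs optional integer epoch indices to use (otherwise all
#'   complete epochs).
#' @return numeric vector of normalized PSI per center frequency
#'   (named by Hz).
#' @export
psi <- function(x, y, fs, cfg = psi_config(), epochs = NULL) {
  stopifnot(length(x) == length(y))
  spe <- round(cfg$epoch_len * fs)
  n_ep_avail <- floor(length(x) / spe)
  if (n_ep_avail < 1) {
    spe <- length(x)
    n_ep_avail <- 1
  }
  if (is.null(epochs)) epochs <- seq_len(n_ep_avail)
  sub <- round(cfg$sub_len * fs)
  df <- fs / sub
  nf <- sub %/% 2 + 1
  f <- (seq_len(nf) - 1) * df
  acc <- numeric(length(cfg$fcs))
  n_used <- 0
  for (e in epochs) {
    e0 <- (e - 1L) * spe + 1L
    e1 <- min(e * spe, length(x))
    starts <- psi_sub_starts(e0, e1, fs, cfg)
    if (length(starts) < 3) next
    Fx <- psi_sub_ffts(x, fs, starts, sub)
    Fy <- psi_sub_ffts(y, fs, starts, sub)
    m <- length(starts)
    full <- psi_from_spectra(Fx, Fy, seq_len(m), f, cfg$fcs,
                             cfg$half_window, df)
    jack <- matrix(0, m, length(cfg$fcs))
    for (j in seq_len(m))
      jack[j, ] <- psi_from_spectra(Fx, Fy, setdiff(seq_len(m), j), f,
                                    cfg$fcs, cfg$half_window, df)
    jse <- sqrt((m - 1) / m * colSums(sweep(jack, 2, colMeans(jack))^2))
    z <- ifelse(jse > 0, full / jse, 0)
    acc <- acc + z
    n_used <- n_used + 1
  }
  if (n_used == 0) stop("no usable epochs for PSI")
  stats::setNames(acc / n_used, cfg$fcs)
}

#' Pairwise and net PSI over a recording
#'
#' Computes the normalized PSI for every channel pair over `n_epochs`
#' randomly selected clean in-stage epochs (seeded; all available epochs
#' with a warning if fewer). The pairwise array is exactly antisymmetric.
#'
#' @param rec a recording.
#' @param ann stage annotation (clean N2 epochs eligible), or NULL to use
#'   all complete epochs.
#' @param cfg a [psi_config()].
#' @param stage stage label to analyze.
#' @return list: `pairwise` (channels x channels x frequencies), `net`
#'   (channels x frequencies), `epochs_used`.
#' @export
psi_matrix <- function(rec, ann = NULL, cfg = psi_config(), stage = "N2") {
  n_ch <- nrow(rec$data)
  fs <- rec$fs
  spe <- round(cfg$epoch_len * fs)
  if (!is.null(ann)) {
    clean <- which(ann$stages == stage &
                     !apply(ann$mask == "dropped", 1, any))
  } else {
    clean <- seq_len(floor(ncol(rec$data) / spe))
  }
  if (length(clean) == 0) stop("no clean epochs")
  eps <- if (length(clean) > cfg$n_epochs) {
    with_seed(cfg$seed, sort(sample(clean, cfg$n_epochs)))
  } else {
    if (length(clean) < cfg$n_epochs)
      warning("fewer than ", cfg$n_epochs, " clean epochs; using all ",
              length(clean))
    clean
  }
  nfc <- length(cfg$fcs)
  pw <- array(0, c(n_ch, n_ch, nfc),
              dimnames = list(rec$channel_names, rec$channel_names, cfg$fcs))
  for (i in seq_len(n_ch - 1)) {
    for (j in (i + 1):n_ch) {
      v <- psi(rec$data[i, ], rec$data[j, ], fs, cfg, epochs = eps)
      pw[i, j, ] <- v
      pw[j, i, ] <- -v
    }
  }
  list(pairwise = pw, net = net_psi(pw), epochs_used = eps)
}

#' Net PSI per channel
#'
#' Sum of pairwise PSI values involving each channel ("sender" positive);
#' sums to zero across channels at every frequency.
#'
#' @param pairwise channels x channels x frequencies antisymmetric array.
#' @return channels x frequencies matrix.
#' @export
net_psi <- function(pairwise) {
  apply(pairwise, 3, rowSums)
}
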