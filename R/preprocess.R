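#' Standard sleep-EEG preprocessing
#'
#' Re-references to linked mastoids (signal minus the mean of the two
#' mastoid channels), resamples to the working rate (200 Hz) and applies a
#' zero-phase FIR bandpass of 0.3-35 Hz. The FIR is applied
#' forward-backward so slow-oscillation morphology is not phase-shifted.
#'
#' @param rec a recording.
#' @param mastoid_labels character(2): the two mastoid channel names, or
#'   NULL with `already_referenced = TRUE`.
#' @param already_referenced set TRUE if the input is already referenced.
#' @param fs_out output rate, Hz.
#' @param band passband edges, Hz.
#' @return preprocessed recording (mastoid channels removed).
#' @export
preprocess <- function(rec, mastoid_labels = NULL, already_referenced = FALSE,
                       fs_out = 200, band = c(0.3, 35)) {
  dat <- rec$data
  nms <- rec$channel_names
  ref <- rec$reference
  if (!is.null(mastoid_labels)) {
    if (!all(mastoid_labels %in% nms))
      stop("mastoid channels not found: ",
           paste(setdiff(mastoid_labels, nms), collapse = ", "))
    m <- colMeans(dat[match(mastoid_labels, nms), , drop = FALSE])
    keep <- !(nms %in% mastoid_labels)
    dat <- sweep(dat[keep, , drop = FALSE], 2, m, "-")
    nms <- nms[keep]
    ref <- "linked-mastoid"
  } else if (!already_referenced) {
    stop("no mastoid channels given; set already_referenced = TRUE if the ",
         "data are already referenced")
  }
  if (rec$fs != fs_out) {
    dat <- t(apply(dat, 1, resample_signal, fs_in = rec$fs, fs_out = fs_out))
  }
  # demean, then a long zero-phase FIR: 1100 taps keeps the transition band
  # narrow enough (~0.6 Hz) that DC sits in the stopband
  for (ch in seq_len(nrow(dat)))
    dat[ch, ] <- bp_filter(dat[ch, ] - mean(dat[ch, ]), fs_out,
                           band[1], band[2], type = "fir", order = 1100L)
  pos <- rec$positions
  if (!is.null(pos) && !is.null(mastoid_labels))
    pos <- pos[!(rec$channel_names %in% mastoid_labels), , drop = FALSE]
  new_recording(dat, fs_out, channel_names = nms, positions = pos,
                reference = ref)
}

#' Hjorth parameters of a signal epoch
#'
#' Activity = variance; mobility = sqrt(var(x') / var(x)); complexity =
#' mobility(x') / mobility(x), with the derivative taken as the first
#' difference scaled by the sampling rate. For a pure tone at frequency f
#' the mobility is 2 fs sin(pi f / fs) ~ 2 pi f.
#'
#' @param x numeric vector (one epoch of one channel).
#' @param fs sampling rate, Hz.
#' @return named numeric: activity (uV^2), mobility, complexity. A constant
#'   signal gives activity 0 and NA mobility/complexity.
#' @export
hjorth <- function(x, fs) {
  if (length(x) < 3) stop("epoch too short for Hjorth parameters")
  v0 <- stats::var(x)
  if (v0 == 0) return(c(activity = 0, mobility = NA_real_,
                        complexity = NA_real_))
  d1 <- diff(x) * fs
  d2 <- diff(d1) * fs
  v1 <- stats::var(d1)
  v2 <- stats::var(d2)
  mob <- sqrt(v1 / v0)
  comp <- if (v1 > 0) sqrt(v2 / v1) / mob else NA_real_
  c(activity = v0, mobility = mob, complexity = comp)
}

#' Spherical-spline interpolation of bad channels
#'
#' Interpolates bad channels from the remaining good channels using the
#' spherical-spline g-function (Legendre expansion, stiffness m = 4,
#' 50 terms, small diagonal regularization).
#'
#' @param rec a recording with unit-sphere `positions`.
#' @param bad_channels indices or names of channels to replace.
#' @param samples optional sample indices to restrict the replacement to.
#' @return recording with bad channels replaced by their spline estimate.
#' @export
interpolate_spherical_spline <- function(rec, bad_channels, samples = NULL) {
  if (is.null(rec$positions)) stop("channel positions required")
  if (is.character(bad_channels))
    bad_channels <- match(bad_channels, rec$channel_names)
  bad_channels <- sort(unique(bad_channels))
  if (length(bad_channels) == 0) return(rec)
  good <- setdiff(seq_len(nrow(rec$data)), bad_channels)
  if (length(good) < 4) stop("need at least 4 good channels with positions")
  if (is.null(samples)) samples <- seq_len(ncol(rec$data))
  pos <- rec$positions / sqrt(rowSums(rec$positions^2))
  cosang_gg <- tcrossprod(pos[good, , drop = FALSE])
  cosang_bg <- pos[bad_channels, , drop = FALSE] %*% t(pos[good, , drop = FALSE])
  G <- spline_g(cosang_gg) + diag(1e-5, length(good))
  A <- rbind(cbind(G, 1), c(rep(1, length(good)), 0))
  V <- rbind(rec$data[good, samples, drop = FALSE], 0)
  sol <- solve(A, V)
  Gb <- spline_g(cosang_bg)
  est <- Gb %*% sol[seq_along(good), , drop = FALSE] +
    matrix(sol[length(good) + 1L, ], nrow = length(bad_channels),
           ncol = length(samples), byrow = TRUE)
  rec$data[bad_channels, samples] <- est
  rec
}

# Perrin et al. spherical-spline g function, stiffness m = 4, 50 terms
spline_g <- function(x, m = 4, n_terms = 50) {
  x <- pmin(pmax(x, -1), 1)
  dims <- dim(x)
  x <- as.numeric(x)
  # Legendre recurrence
  p_prev <- rep(1, length(x))
  p_cur <- x
  out <- numeric(length(x))
  for (n in 1:n_terms) {
    if (n == 1) pn <- p_cur
    else {
      pn <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
      p_prev <- p_cur
      p_cur <- pn
    }
    out <- out + (2 * n + 1) / (n^m * (n + 1)^m) * pn
  }
  out <- out / (4 * pi)
  dim(out) <- dims
  out
}
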