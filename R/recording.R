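#' Multichannel EEG recording
#'
#' Lightweight container for a multichannel signal: a channels x samples
#' matrix in microvolts, a sampling rate, channel names and (optionally)
#' unit-sphere sensor positions used for spherical-spline interpolation.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one per row of `data`.
#' @param positions optional channels x 3 matrix of unit-sphere coordinates.
#' @param reference label describing the current reference ("raw",
#'   "linked-mastoid", ...).
#' @return an object of class `recording`.
#' @export
new_recording <- function(data, fs, channel_names = NULL, positions = NULL,
                          reference = "raw") {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("fs must be a positive scalar")
  if (is.null(channel_names))
    channel_names <- paste0("CH", seq_len(nrow(data)))
  if (length(channel_names) != nrow(data))
    stop("channel_names length must match number of channels")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nrow(data) || ncol(positions) != 3)
      stop("positions must be channels x 3")
  }
  if (anyNA(data)) stop("data contains NA")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 positions = positions, reference = reference),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

#' Sleep-stage annotation
#'
#' Per-epoch sleep-stage labels (30-s epochs by convention) plus a per-epoch,
#' per-channel status mask recording artifact handling: "clean",
#' "interpolated" or "dropped". Dropped epochs are dropped for all channels.
#'
#' @param stages character vector of stage labels, one per epoch
#'   (W, N1, N2, N3, R).
#' @param epoch_len epoch length in seconds (default 30).
#' @param n_channels number of channels covered by the mask.
#' @param mask optional epochs x channels character matrix; defaults to all
#'   "clean".
#' @return an object of class `stage_annotation`.
#' @export
new_stage_annotation <- function(stages, epoch_len = 30, n_channels = 1,
                                 mask = NULL) {
  stages <- as.character(stages)
  if (!all(stages %in% c("W", "N1", "N2", "N3", "R", "?")))
    stop("unknown stage label")
  if (is.null(mask))
    mask <- matrix("clean", nrow = length(stages), ncol = n_channels)
  stopifnot(nrow(mask) == length(stages))
  structure(list(stages = stages, epoch_len = epoch_len, mask = mask),
            class = "stage_annotation")
}

#' @export
print.stage_annotation <- function(x, ...) {
  tab <- table(x$stages)
  cat(sprintf("<stage_annotation> %d x %gs epochs (%s); %d dropped\n",
              length(x$stages), x$epoch_len,
              paste(names(tab), tab, sep = ":", collapse = " "),
              sum(apply(x$mask == "dropped", 1, any))))
  invisible(x)
}

#' Per-sample logical mask of clean samples in a given stage
#'
#' @param ann a `stage_annotation`.
#' @param fs sampling rate of the recording the mask applies to.
#' @param n_samples total sample count of that recording.
#' @param stage stage label to select (default "N2").
#' @param channel channel index for per-channel mask status (interpolated
#'   epochs count as clean; dropped never do).
#' @return logical vector of length `n_samples`.
#' @export
stage_sample_mask <- function(ann, fs, n_samples, stage = "N2", channel = 1) {
  spe <- round(ann$epoch_len * fs)
  keep <- logical(n_samples)
  ch <- min(channel, ncol(ann$mask))
  for (e in seq_along(ann$stages)) {
    if (ann$stages[e] != stage) next
    if (ann$mask[e, ch] == "dropped") next
    i0 <- (e - 1L) * spe + 1L
    i1 <- min(e * spe, n_samples)
    if (i0 <= n_samples) keep[i0:i1] <- TRUE
  }
  keep
}

epoch_indices <- function(epoch, fs, epoch_len = 30) {
  spe <- round(epoch_len * fs)
  ((epoch - 1L) * spe + 1L):(epoch * spe)
}
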