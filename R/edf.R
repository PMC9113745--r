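#' EDF (European Data Format) I/O
#'
#' Minimal EDF reader/writer for continuous multichannel recordings:
#' 16-bit samples, one-second data records, physical dimension microvolts.
#' Signals are stored with a symmetric physical range per channel, so a
#' write/read round trip is exact to within one quantization step of that
#' range.
#'
#' @param rec a [new_recording()] object; `fs` must be a whole number and
#'   the duration a whole number of seconds (truncated otherwise).
#' @param path file path.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns a
#'   `recording`.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (fs != round(fs)) stop("write_edf needs an integer sampling rate")
  ns <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  dat <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  pmax_ <- apply(abs(dat), 1, max)
  pmax_[pmax_ == 0] <- 1
  # header fields are 8 ascii chars; digitize against the value as written
  pmax_ <- round(pmax_ + 0.005, 2)
  dmax <- 32767L
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (nm in rec$channel_names) wr(substr(nm, 1, 16), 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.2f", -pmax_[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.2f", pmax_[i]), 8)
  for (i in seq_len(ns)) wr(-dmax, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  dig <- round(sweep(dat, 1, dmax / pmax_, "*"))
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns))
      writeBin(as.integer(dig[i, idx]), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # physical dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  fs <- spr / rec_dur
  if (length(unique(fs)) != 1)
    stop("channels have different sampling rates; resample before reading")
  dat <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[i], size = 2, endian = "little")
      phys <- (dig - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i]) +
        pmin_[i]
      dat[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <- phys
    }
  }
  new_recording(dat, fs[1], channel_names = labels)
}

#' Read/write sleep-stage annotation TSVs
#'
#' Stage files have columns `epoch_index` (1-based) and `stage`; mask files
#' have `epoch_index`, `channel`, `status`.
#'
#' @param ann a stage annotation; `path` a file path.
#' @return `read_stage_tsv` returns a `stage_annotation`.
#' @export
write_stage_tsv <- function(ann, path) {
  utils::write.table(
    data.frame(epoch_index = seq_along(ann$stages), stage = ann$stages),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stage_tsv
#' @param n_channels channels for the (all-clean) mask of the returned
#'   annotation.
#' @export
read_stage_tsv <- function(path, n_channels = 1) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_stage_annotation(df$stage[order(df$epoch_index)],
                       n_channels = n_channels)
}
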