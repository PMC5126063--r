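#' Write an EEG recording to European Data Format (EDF)
#'
#' Minimal EDF export: 16-bit integer encoding, one-second data records,
#' per-channel physical scaling chosen from the data range. The montage
#' (positions, roles) is not representable in EDF; write it alongside with
#' [write_montage()].
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  if (n_rec * fs < ncol(rec$data))
    warning("trailing partial second dropped in EDF export")
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmax_ <- apply(abs(x), 1, max)
  pmax_ <- ifelse(pmax_ > 0, pmax_ * 1.0001, 1)
  dmin <- -32768L; dmax <- 32767L
  dig <- round(sweep(x, 1, pmax_ / 32767, "/"))

  pad <- function(s, w) {
    s <- substr(as.character(s), 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (ns + 1), 8), pad("", 44), pad(n_rec, 8), pad("1", 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste(vapply(vals, pad, "", w = w),
                                           collapse = ""), con, eos = NULL)
  fld(rec$channel_labels, 16)
  fld(rep("AgAgCl electrode", ns), 80)
  fld(rep("uV", ns), 8)
  fld(sprintf("%.6g", -pmax_), 8)
  fld(sprintf("%.6g", pmax_), 8)
  fld(rep(dmin, ns), 8)
  fld(rep(dmax, ns), 8)
  fld(rep("", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports the plain-EDF subset used by this package (uniform one-second
#' records, identical sampling rate on every signal).
#'
#' @param path EDF file path.
#' @param montage optional data.frame from [read_montage()] restoring
#'   positions and roles; without it, positions default to a generated montage.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path, montage = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1) stop("mixed sampling rates not supported")
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, "integer", n = ns * spr[1], size = 2, endian = "little")
    out[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      matrix(blk, nrow = ns, byrow = TRUE)
  }
  scale_ <- (pmax_ - pmin_) / (dmax - dmin)
  out <- sweep(sweep(out, 1, (dmax + dmin) / 2, "-"), 1, scale_, "*")
  if (is.null(montage)) {
    m <- make_montage(ns)
    pos <- m$positions; roles <- m$roles
  } else {
    stopifnot(all(montage$label == labels))
    pos <- as.matrix(montage[, c("x", "y", "z")])
    roles <- montage$role
  }
  eeg_recording(out, fs, labels, pos, roles)
}
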