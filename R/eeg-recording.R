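#' Multichannel EEG recording container
#'
#' A lightweight container for a continuous multichannel EEG recording:
#' a channels-by-samples matrix in microvolts, its sampling rate, channel
#' labels, unit-sphere electrode positions, a per-channel role flag
#' (`"active"`, `"occipital"`, `"reference"` or `"bad"`), and the name of the
#' reference electrode.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate sampling rate in Hz; must exceed 60 Hz so that the
#'   30 Hz upper analysis frequency is below Nyquist.
#' @param channel_labels character vector of channel names, one per row.
#' @param channel_positions numeric matrix, channels x 3, unit-norm electrode
#'   coordinates (x right, y anterior, z superior).
#' @param roles character vector of per-channel roles in
#'   `c("active", "occipital", "reference", "bad")`; exactly one `"reference"`.
#' @param reference_label name of the reference channel.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels,
                          channel_positions, roles,
                          reference_label = channel_labels[roles == "reference"][1]) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("EEG data must be finite")
  if (sampling_rate <= 60) stop("sampling_rate must exceed 2x the 30 Hz analysis band")
  if (length(channel_labels) != nrow(data)) stop("one label per channel required")
  channel_positions <- as.matrix(channel_positions)
  if (nrow(channel_positions) != nrow(data) || ncol(channel_positions) != 3)
    stop("channel_positions must be channels x 3")
  nrm <- sqrt(rowSums(channel_positions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("channel positions must have unit norm")
  roles <- match.arg(roles, c("active", "occipital", "reference", "bad"),
                     several.ok = TRUE)
  if (length(roles) != nrow(data)) stop("one role per channel required")
  if (sum(roles == "reference") != 1) stop("exactly one reference channel required")
  rownames(data) <- channel_labels
  structure(list(
    data = data,
    sampling_rate = sampling_rate,
    channel_labels = channel_labels,
    channel_positions = channel_positions,
    roles = roles,
    reference_label = reference_label
  ), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat(sprintf("  roles: %s; reference: %s\n",
              paste(sprintf("%s=%d", names(table(x$roles)), table(x$roles)),
                    collapse = ", "),
              x$reference_label))
  invisible(x)
}

#' Build a labelled reduced montage on the upper unit hemisphere
#'
#' Places `n_channels` electrodes quasi-uniformly on the upper hemisphere with
#' a Fibonacci lattice, assigns the channel nearest the vertex as the reference
#' (the Cz position of the acquisition montage), marks the most posterior
#' channels as occipital, and labels the most anterior tenth as frontal (used
#' by the blink simulator and the automated blink-component criterion).
#'
#' @param n_channels number of electrodes (>= 8).
#' @param occipital_fraction fraction of channels (most negative y) flagged
#'   with the `"occipital"` role.
#' @return list with `labels`, `positions` (n x 3), `roles`,
#'   `frontal` (logical: anterior tenth) and `reference_label`.
#' @export
make_montage <- function(n_channels, occipital_fraction = 0.12) {
  if (n_channels < 8) stop("need at least 8 channels")
  i <- seq_len(n_channels) - 0.5
  phi <- (1 + sqrt(5)) / 2
  z <- i / n_channels              # upper hemisphere only
  r <- sqrt(pmax(0, 1 - z^2))
  th <- 2 * pi * i / phi
  pos <- cbind(x = r * cos(th), y = r * sin(th), z = z)
  labels <- sprintf("E%03d", seq_len(n_channels))
  roles <- rep("active", n_channels)
  roles[which.max(pos[, "z"])] <- "reference"
  n_occ <- max(2L, round(occipital_fraction * n_channels))
  occ <- order(pos[, "y"])[seq_len(n_occ)]
  occ <- setdiff(occ, which(roles == "reference"))
  roles[occ] <- "occipital"
  n_front <- max(2L, ceiling(0.10 * n_channels))
  frontal <- rep(FALSE, n_channels)
  frontal[setdiff(order(pos[, "y"], decreasing = TRUE),
                  which(roles == "reference"))[seq_len(n_front)]] <- TRUE
  list(labels = labels, positions = pos, roles = roles, frontal = frontal,
       reference_label = labels[roles == "reference"])
}

#' Identify the designated frontal channels of a recording
#'
#' Frontal channels are the most anterior tenth of non-reference electrodes
#' (position y-coordinate); they host simulated blinks and anchor the
#' frontal-loading criterion of [remove_blink_components()].
#'
#' @param rec an [eeg_recording()].
#' @return character vector of channel labels.
#' @export
frontal_channels <- function(rec) {
  n_front <- max(2L, ceiling(0.10 * nrow(rec$data)))
  ord <- order(rec$channel_positions[, 2], decreasing = TRUE)
  ord <- setdiff(ord, which(rec$roles == "reference"))
  rec$channel_labels[ord[seq_len(n_front)]]
}

#' Write / read a montage table
#'
#' Tab-separated with columns `label, x, y, z, role`.
#'
#' @param rec an [eeg_recording()].
#' @param path file path.
#' @return `write_montage` returns `path` invisibly; `read_montage` returns a
#'   data.frame.
#' @export
write_montage <- function(rec, path) {
  df <- data.frame(label = rec$channel_labels,
                   x = rec$channel_positions[, 1],
                   y = rec$channel_positions[, 2],
                   z = rec$channel_positions[, 3],
                   role = rec$roles)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
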