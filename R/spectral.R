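# DPSS tapers by the standard tridiagonal formulation, with concentration
# eigenvalues from the sinc kernel. Cached per (n, nw, k).
.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw, k) {
  key <- paste(n, nw, k, sep = "_")
  hit <- .dpss_cache[[key]]
  if (!is.null(hit)) return(hit)
  t <- 0:(n - 1)
  d <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * nw / n)
  e <- t[-1] * (n - t[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- d
  A[cbind(2:n, 1:(n - 1))] <- e
  A[cbind(1:(n - 1), 2:n)] <- e
  eg <- eigen(A, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) if (sum(v[, j]) < 0) v[, j] <- -v[, j]
  W <- nw / n
  i <- outer(t, t, "-")
  S <- ifelse(i == 0, 2 * W, sin(2 * pi * W * i) / (pi * i))
  lam <- vapply(seq_len(k), function(j) drop(crossprod(v[, j], S %*% v[, j])), 0)
  res <- list(tapers = v, eigenvalues = lam)
  .dpss_cache[[key]] <- res
  res
}

#' Frequency band definitions
#'
#' The five analysis bands — delta 1-4, theta 4-8, alpha1 8-10, alpha2 10-13,
#' beta 13-30 Hz — under the half-open convention `[low, high)` (a 10 Hz bin
#' belongs to alpha2, not alpha1), plus the total range used as the
#' relative-power denominator. The default denominator is 1-30 Hz, the union
#' of the five bands, so the five fractions sum to 1.
#'
#' @param bands named list of `c(low, high)` pairs.
#' @param total `c(low, high)` normalisation range.
#' @return list of class `band_set`.
#' @export
band_set <- function(bands = list(delta = c(1, 4), theta = c(4, 8),
                                  alpha1 = c(8, 10), alpha2 = c(10, 13),
                                  beta = c(13, 30)),
                     total = c(1, 30)) {
  edges <- do.call(rbind, bands)
  if (any(edges[, 1] >= edges[, 2])) stop("band low must be < high")
  o <- order(edges[, 1])
  if (any(edges[o, 2][-nrow(edges)] > edges[o, 1][-1] + 1e-12))
    stop("bands overlap under the half-open convention")
  if (min(edges[, 1]) < total[1] - 1e-12 || max(edges[, 2]) > total[2] + 1e-12)
    stop("band union must lie within the total range")
  structure(list(bands = bands, total = total), class = "band_set")
}

#' Multitaper power spectral density per channel
#'
#' Epochs the recording (default 4 s epochs, 50% overlap), applies discrete
#' prolate spheroidal (Slepian) tapers with time half-bandwidth
#' `epoch_length * half_bandwidth` and `2*NW - 1` tapers, and averages the
#' eigenvalue-weighted eigenspectra over tapers and epochs. The estimate is
#' a one-sided density in signal-units squared per Hz, so its integral over
#' frequency equals the signal variance (Parseval).
#'
#' @param rec an [eeg_recording()] (preprocessed).
#' @param epoch_length epoch length in seconds.
#' @param half_bandwidth spectral half-bandwidth W in Hz; the default 0.5 Hz
#'   with 4 s epochs gives NW = 2 and 3 tapers.
#' @param overlap fractional epoch overlap.
#' @return list of class `psd_matrix`: `power` (channels x bins, uV^2/Hz),
#'   `freqs` (Hz), `epoch_count`, `taper_count`, plus the channel labels and
#'   roles of the recording.
#' @export
multitaper_psd <- function(rec, epoch_length = 4, half_bandwidth = 0.5,
                           overlap = 0.5) {
  fs <- rec$sampling_rate
  nep <- as.integer(round(epoch_length * fs))
  if (ncol(rec$data) < nep) stop("recording shorter than one epoch")
  nw <- epoch_length * half_bandwidth
  k <- max(1L, as.integer(floor(2 * nw - 1)))
  if (nep < 2 * k) stop("epoch too short for the taper order")
  tp <- dpss_tapers(nep, nw, k)
  lam <- tp$eigenvalues
  step <- max(1L, as.integer(round(nep * (1 - overlap))))
  starts <- seq(1L, ncol(rec$data) - nep + 1L, by = step)
  nf <- nep %/% 2 + 1L
  nch <- nrow(rec$data)
  acc <- matrix(0, nch, nf)
  for (s in starts) {
    seg <- rec$data[, s:(s + nep - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    psd_e <- matrix(0, nch, nf)
    for (j in seq_len(k)) {
      tap <- matrix(tp$tapers[, j], nch, nep, byrow = TRUE)
      F_ <- stats::mvfft(t(seg * tap))
      psd_e <- psd_e + lam[j] * t(abs(F_[seq_len(nf), , drop = FALSE])^2) / fs
    }
    acc <- acc + psd_e / sum(lam)
  }
  power <- acc / length(starts)
  power[, 2:(nf - 1)] <- 2 * power[, 2:(nf - 1)]  # one-sided
  structure(list(power = power, freqs = (seq_len(nf) - 1) * fs / nep,
                 epoch_count = length(starts), taper_count = k,
                 channel_labels = rec$channel_labels, roles = rec$roles),
            class = "psd_matrix")
}

#' Global median spectrum across active channels
#'
#' Per-frequency median of the PSD across scalp channels (roles `"active"`
#' and `"occipital"`); `"bad"` and `"reference"` channels are excluded.
#'
#' @param psd a `psd_matrix` from [multitaper_psd()].
#' @param roles optional role vector overriding the one stored in `psd`.
#' @return numeric vector, one value per frequency bin.
#' @export
global_median_spectrum <- function(psd, roles = psd$roles) {
  use <- roles %in% c("active", "occipital")
  if (!any(use)) stop("no active channels")
  apply(psd$power[use, , drop = FALSE], 2, stats::median)
}

#' Relative band power of a spectrum
#'
#' Integrates the spectrum over each band (`[low, high)` bin-centre
#' assignment) and divides by the integral over the total range, yielding
#' the global relative median power (GRMP) fractions when applied to the
#' global median spectrum.
#'
#' @param spectrum numeric vector of spectral power.
#' @param freqs frequency grid (Hz) matching `spectrum`.
#' @param bands a [band_set()].
#' @return named numeric vector of fractions, one per band.
#' @export
band_relative_power <- function(spectrum, freqs, bands = band_set()) {
  if (min(freqs) > bands$total[1] || max(freqs) < bands$total[2])
    stop("spectrum grid does not cover the total range")
  tot_idx <- freqs >= bands$total[1] & freqs < bands$total[2]
  denom <- sum(spectrum[tot_idx])
  if (denom <= 0) stop("undefined feature: zero total power")
  vapply(bands$bands, function(b) {
    sum(spectrum[freqs >= b[1] & freqs < b[2]]) / denom
  }, 0)
}

#' Occipital median frequency
#'
#' Median of the occipital power distribution over 4-14 Hz: the
#' across-occipital-channels median spectrum is restricted to the range and
#' the frequency at which cumulative power first reaches half of the
#' restricted total is returned, with linear interpolation within the
#' crossing bin.
#'
#' @param psd a `psd_matrix` from [multitaper_psd()].
#' @param roles optional role vector override.
#' @param range frequency range, default `c(4, 14)` Hz.
#' @return median frequency in Hz.
#' @export
occipital_median_frequency <- function(psd, roles = psd$roles,
                                       range = c(4, 14)) {
  occ <- roles == "occipital"
  if (!any(occ)) stop("no occipital channels")
  spec <- apply(psd$power[occ, , drop = FALSE], 2, stats::median)
  df <- psd$freqs[2] - psd$freqs[1]
  idx <- which(psd$freqs >= range[1] & psd$freqs < range[2])
  mass <- spec[idx]
  tot <- sum(mass)
  if (tot <= 0) stop("undefined feature: zero power in range")
  cs <- cumsum(mass)
  j <- which(cs >= tot / 2)[1]
  lo_edge <- psd$freqs[idx[j]] - df / 2
  prev <- if (j > 1) cs[j - 1] else 0
  # linear interpolation within the crossing bin
  lo_edge + df * (tot / 2 - prev) / mass[j]
}

#' Extract the qEEG biomarkers of a recording
#'
#' Convenience wrapper: multitaper PSD, global median spectrum, GRMP per
#' band, and occipital median frequency.
#'
#' @param rec a preprocessed [eeg_recording()].
#' @param bands a [band_set()].
#' @param ... passed to [multitaper_psd()].
#' @return one-row data.frame with `grmp_delta` ... `grmp_beta` (fractions)
#'   and `occipital_mf_hz`.
#' @export
spectral_features <- function(rec, bands = band_set(), ...) {
  psd <- multitaper_psd(rec, ...)
  gms <- global_median_spectrum(psd)
  grmp <- band_relative_power(gms, psd$freqs, bands)
  mf <- occipital_median_frequency(psd)
  out <- as.data.frame(as.list(stats::setNames(grmp, paste0("grmp_", names(grmp)))))
  out$occipital_mf_hz <- mf
  out
}
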