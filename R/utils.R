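#' @keywords internal
"_PACKAGE"

# Sample (raw, non-excess) kurtosis; Gaussian data -> ~3.
kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 <= 0) return(0)
  mean(x^4) / m2^2
}

#' Derive a sub-stream seed from a master seed
#'
#' Deterministically maps a (master seed, stream index) pair to a new seed
#' below 2^31, so one integer reproduces an entire multi-stage run while
#' independent random stages stay decoupled.
#'
#' @param seed master integer seed.
#' @param stream integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647L)
}

# FFT-based linear convolution, "same" alignment after a given delay.
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) *
                       stats::fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_len(n)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
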