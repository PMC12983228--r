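#' Continuous wavelet transform scalogram
#'
#' Computes the magnitude scalogram of a signal under the analytic Morlet
#' wavelet (centre frequency omega0 = 6), the time-frequency image the
#' R-peak segmentation model takes as input. Scales are log-spaced so their
#' pseudo-frequencies span `freq_range` (default 1–45 Hz, covering the
#' P/QRS/T energy band); pseudo-frequencies decrease strictly with scale
#' index. The transform is evaluated in the Fourier domain with zero-padding
#' to the next power of two.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param n_scales number of scales (rows).
#' @param freq_range pseudo-frequency span in Hz, `c(low, high)`.
#' @return a `scalogram`: list with `magnitude` (n_scales x n matrix, row 1 =
#'   highest pseudo-frequency), `freqs_hz`, `scales_s`, and `rate`.
#' @export
cwt_scalogram <- function(x, rate, n_scales = 64L, freq_range = c(1, 45)) {
  if (length(x) == 0L) stop_param("empty signal")
  assert_scalar_num(rate, "rate", lower = 1e-9)
  omega0 <- 6
  # Morlet Fourier factor: scale * fourier_factor = Fourier period
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  freqs <- exp(seq(log(freq_range[2]), log(freq_range[1]), length.out = n_scales))
  scales <- 1 / (fourier_factor * freqs)   # seconds

  n <- length(x)
  # pad to at least 2n so the transform is a linear, not circular, convolution
  npad <- 2^ceiling(log2(max(2 * n, 4)))
  xf <- fft(c(x, rep(0, npad - n)))
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, k, k - npad) * 2 * pi * rate / npad

  mag <- matrix(0, nrow = n_scales, ncol = n)
  pos <- omega > 0
  dt <- 1 / rate
  for (j in seq_len(n_scales)) {
    s <- scales[j]
    psi_hat <- numeric(npad)
    # analytic Morlet daughter, L2-normalized (Torrence & Compo norm)
    psi_hat[pos] <- sqrt(2 * pi * s / dt) * pi^(-0.25) *
      exp(-((s * omega[pos] - omega0)^2) / 2)
    w <- fft(xf * psi_hat, inverse = TRUE) / npad
    # sqrt(dt) factor: magnitudes equal the continuous convolution
    # |s^{-1/2} \int x(t') psi*((t'-t)/s) dt'| (the daughter normalization
    # above carries a 1/sqrt(dt))
    mag[j, ] <- Mod(w[seq_len(n)]) * sqrt(dt)
  }
  structure(list(magnitude = mag, freqs_hz = freqs, scales_s = scales,
                 rate = rate),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d scales (%.2f–%.2f Hz) x %d samples @ %g Hz\n",
              nrow(x$magnitude), min(x$freqs_hz), max(x$freqs_hz),
              ncol(x$magnitude), x$rate))
  invisible(x)
}
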