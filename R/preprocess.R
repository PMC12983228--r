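#' Butterworth filter specification
#'
#' The preprocessing chain uses two second-order IIR Butterworth filters at
#' 500 Hz: a 0.5–100 Hz band-pass that removes baseline wander and
#' out-of-band high-frequency content, followed by a 49–51 Hz band-stop that
#' suppresses mains interference.
#'
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @param order filter order (>= 1); the default chain uses order 2.
#' @return a `filter_spec` object.
#' @export
filter_spec <- function(kind = c("bandpass", "bandstop"), low, high, order = 2L) {
  kind <- match.arg(kind)
  assert_scalar_num(low, "low", lower = 1e-9)
  assert_scalar_num(high, "high")
  if (high <= low) stop_param("band edges must satisfy 0 < low < high")
  assert_scalar_num(order, "order", lower = 1)
  structure(list(kind = kind, low = low, high = high, order = as.integer(order),
                 design = "butterworth"),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
default_bandpass <- function() filter_spec("bandpass", 0.5, 100, 2L)

#' @rdname filter_spec
#' @export
default_bandstop <- function() filter_spec("bandstop", 49, 51, 2L)

butter_coefs <- function(spec, rate) {
  if (spec$high >= rate / 2) {
    stop_param("upper band edge %g Hz must be below the Nyquist frequency %g Hz",
               spec$high, rate / 2)
  }
  type <- if (spec$kind == "bandpass") "pass" else "stop"
  signal::butter(spec$order, c(spec$low, spec$high) / (rate / 2), type = type)
}

# Zero-phase (forward-backward) filtering with odd-reflection edge padding of
# 3 x rate samples (capped at n - 1). Doubles the effective order; applied
# identically to both channels so pairwise metrics see no group delay.
zero_phase_filter <- function(filt, x, rate) {
  n <- length(x)
  min_n <- 3L * (2L * length(filt$b))
  if (n < min_n) {
    stop_param("signal too short to filter: %d samples, need at least %d", n, min_n)
  }
  pad <- min(n - 1L, as.integer(3 * rate))
  left <- 2 * x[1] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(pad + 1L):(pad + n)]
}

#' Band-pass filter an ECG signal
#'
#' Applies the Butterworth band-pass zero-phase (forward-backward, with
#' odd-reflection padding), so filtered peaks do not shift in time.
#'
#' @param x numeric signal (mV).
#' @param rate sampling rate in Hz.
#' @param spec a band-pass [filter_spec()]; defaults to 0.5–100 Hz, order 2.
#' @return filtered signal, same length as `x`.
#' @export
ecg_bandpass <- function(x, rate, spec = default_bandpass()) {
  if (spec$kind != "bandpass") stop_param("`spec` must be a bandpass filter_spec")
  zero_phase_filter(butter_coefs(spec, rate), x, rate)
}

#' Band-stop (notch) filter an ECG signal
#'
#' @inheritParams ecg_bandpass
#' @param spec a band-stop [filter_spec()]; defaults to 49–51 Hz, order 2.
#' @return filtered signal, same length as `x`.
#' @export
ecg_bandstop <- function(x, rate, spec = default_bandstop()) {
  if (spec$kind != "bandstop") stop_param("`spec` must be a bandstop filter_spec")
  zero_phase_filter(butter_coefs(spec, rate), x, rate)
}

#' Squared magnitude response of the zero-phase filter
#'
#' Analytic oracle for the filtering contracts: the gain a zero-phase
#' (forward-backward) pass applies to a steady sinusoid at `freq` is the
#' squared magnitude of the underlying one-pass filter there.
#'
#' @param spec a [filter_spec()].
#' @param rate sampling rate in Hz.
#' @param freq frequencies (Hz) at which to evaluate.
#' @return numeric vector of gains (amplitude ratio for the zero-phase pass).
#' @export
filter_gain <- function(spec, rate, freq) {
  filt <- butter_coefs(spec, rate)
  w <- 2 * pi * freq / rate
  z <- exp(1i * w)
  h <- vapply(z, function(zz) {
    sum(filt$b * zz^(-(seq_along(filt$b) - 1))) /
      sum(filt$a * zz^(-(seq_along(filt$a) - 1)))
  }, complex(1))
  Mod(h)^2
}

#' Preprocess an ECG record
#'
#' Band-pass 0.5–100 Hz then band-stop 49–51 Hz, both Butterworth order 2,
#' applied zero-phase. Works on an [ecg_record()] (metadata preserved), a
#' `labeled_record` (annotations preserved), or a bare numeric vector with
#' `rate` supplied.
#'
#' @param record an `ecg_record`, `labeled_record`, or numeric vector.
#' @param rate sampling rate in Hz (required for a bare vector).
#' @param bandpass,bandstop filter specifications.
#' @return same type as the input, with filtered samples.
#' @export
preprocess_record <- function(record, rate = NULL,
                              bandpass = default_bandpass(),
                              bandstop = default_bandstop()) {
  run <- function(x, r) ecg_bandstop(ecg_bandpass(x, r, bandpass), r, bandstop)
  if (inherits(record, "ecg_record")) {
    record$samples <- run(record$samples, record$rate)
    record
  } else if (inherits(record, "labeled_record")) {
    record$signal <- run(record$signal, record$rate)
    record
  } else if (is.numeric(record)) {
    if (is.null(rate)) stop_param("`rate` is required when filtering a bare vector")
    run(record, rate)
  } else {
    stop_param("unsupported input to preprocess_record")
  }
}
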