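#' Extract fixed cardiac-period windows around R-peaks
#'
#' Cuts one 700 ms window per R-peak, from 250 ms before to 450 ms after the
#' peak (half-open on the right). At 500 Hz each window is 350 samples long
#' with the R sample at local index 125 (0-based; 126 in R's 1-based
#' indexing). Peaks whose window would cross a record edge are skipped and
#' counted.
#'
#' @param signal numeric signal (mV), typically preprocessed.
#' @param rate sampling rate in Hz.
#' @param rpeaks an `rpeak_set` or integer vector of R sample indices
#'   (1-based).
#' @param pre_ms,post_ms window extent before/after the R-peak (ms).
#' @return a `cardiac_period_set`: list with `beats` (n_beats x n_samples
#'   matrix), `rate`, `r_local` (1-based local R index), `source_idx`,
#'   `n_skipped`.
#' @export
extract_periods <- function(signal, rate, rpeaks, pre_ms = 250, post_ms = 450) {
  idx <- if (inherits(rpeaks, "rpeak_set")) accepted_peaks(rpeaks) else as.integer(rpeaks)
  if (any(diff(idx) <= 0)) stop_param("R indices must be strictly increasing")
  pre_n <- ms_to_samples(pre_ms, rate)
  win_n <- ms_to_samples(pre_ms + post_ms, rate)
  n <- length(signal)
  starts <- idx - pre_n
  ok <- starts >= 1L & (starts + win_n - 1L) <= n
  kept <- idx[ok]
  beats <- if (length(kept)) {
    t(vapply(kept, function(i) signal[(i - pre_n):(i - pre_n + win_n - 1L)],
             numeric(win_n)))
  } else {
    matrix(numeric(0), 0, win_n)
  }
  structure(list(beats = beats, rate = rate, pre_ms = pre_ms, post_ms = post_ms,
                 r_local = pre_n + 1L, source_idx = kept,
                 n_skipped = sum(!ok)),
            class = "cardiac_period_set")
}

#' @export
print.cardiac_period_set <- function(x, ...) {
  cat(sprintf("<cardiac_period_set> %d beats x %d samples (%d skipped at edges)\n",
              nrow(x$beats), ncol(x$beats), x$n_skipped))
  invisible(x)
}

#' Median cardiac period
#'
#' The sample-wise median across all extracted beat windows — a beat
#' template robust to transient artifacts in up to half of the beats at any
#' one sample — plus its min–max normalization to \[0, 1\].
#'
#' @param periods a `cardiac_period_set` with at least one beat.
#' @return an `mcp`: list with `raw` (mV), `normalized` (\[0, 1\]),
#'   `r_index` (1-based local R index), `n_beats`, `rate`.
#' @export
compute_mcp <- function(periods) {
  if (!inherits(periods, "cardiac_period_set")) {
    stop_param("`periods` must be a cardiac_period_set")
  }
  if (nrow(periods$beats) < 1L) stop_param("no usable beats to form an MCP")
  raw <- apply(periods$beats, 2, median)
  rng <- range(raw)
  if (rng[1] == rng[2]) stop_param("degenerate MCP: constant raw median")
  structure(list(raw = raw, normalized = (raw - rng[1]) / (rng[2] - rng[1]),
                 r_index = periods$r_local, n_beats = nrow(periods$beats),
                 rate = periods$rate),
            class = "mcp")
}

#' @export
print.mcp <- function(x, ...) {
  cat(sprintf("<mcp> %d samples @ %g Hz from %d beats; R amplitude %.4f mV\n",
              length(x$raw), x$rate, x$n_beats, x$raw[x$r_index]))
  invisible(x)
}

#' P/QRS/T segment windows
#'
#' Half-open windows in ms relative to the R-peak delimiting the three
#' scored sub-segments of the median cardiac period. The defaults
#' (P \[-250, -60), QRS \[-60, +60), T \[+120, +450)) are configurable; P
#' must precede QRS, QRS must contain the R-peak, and QRS must precede T.
#'
#' @param p,qrs,t numeric length-2 `c(start_ms, end_ms)` windows.
#' @return a `segment_windows` object.
#' @export
segment_windows <- function(p = c(-250, -60), qrs = c(-60, 60),
                            t = c(120, 450)) {
  for (w in list(p, qrs, t)) {
    if (!is.numeric(w) || length(w) != 2L || w[1] >= w[2]) {
      stop_param("each window must be c(start_ms, end_ms) with start < end")
    }
  }
  if (p[2] > qrs[1]) stop_param("P window must precede the QRS window")
  if (qrs[2] > t[1]) stop_param("QRS window must precede the T window")
  if (!(qrs[1] <= 0 && qrs[2] > 0)) stop_param("QRS window must contain the R-peak (0 ms)")
  structure(list(P = p, QRS = qrs, T = t), class = "segment_windows")
}

segment_indices <- function(mcp, windows) {
  stopifnot(inherits(mcp, "mcp"))
  n <- length(mcp$raw)
  one <- function(w) {
    lo <- mcp$r_index + ms_to_samples(w[1], mcp$rate)
    hi <- mcp$r_index + ms_to_samples(w[2], mcp$rate) - 1L
    if (lo < 1L || hi > n) stop_param("segment window [%g, %g) ms falls outside the MCP", w[1], w[2])
    lo:hi
  }
  list(MCP = seq_len(n), P = one(windows$P), QRS = one(windows$QRS),
       T = one(windows$T))
}

#' Slice an MCP into scored segments
#'
#' Returns the four waveforms scored downstream: the full MCP and its P,
#' QRS and T sub-segments, all cut with identical index arithmetic so that
#' test and reference slices stay aligned.
#'
#' @param mcp an `mcp`.
#' @param windows a [segment_windows()].
#' @param use_normalized slice the normalized (default) or raw waveform.
#' @return named list of numeric vectors: `MCP`, `P`, `QRS`, `T`.
#' @export
slice_segments <- function(mcp, windows = segment_windows(),
                           use_normalized = TRUE) {
  idx <- segment_indices(mcp, windows)
  src <- if (use_normalized) mcp$normalized else mcp$raw
  lapply(idx, function(i) src[i])
}

#' R-peak amplitude difference between test and reference MCPs
#'
#' Reads the R amplitude at the R index of each raw (unnormalized) MCP and
#' reports the absolute difference in mV — the amplitude-fidelity parameter
#' that complements the shape-based indices. Accepts either `mcp` objects
#' or bare R amplitudes in mV.
#'
#' @param test_mcp,reference_mcp `mcp` objects, or single numeric R
#'   amplitudes (mV).
#' @return an `amplitude_delta`: list with `test_mv`, `reference_mv`,
#'   `delta_mv` (absolute difference).
#' @export
#' @examples
#' amplitude_difference(1.0605, 1.0631)$delta_mv # 0.0026
amplitude_difference <- function(test_mcp, reference_mcp) {
  amp <- function(m, name) {
    if (inherits(m, "mcp")) m$raw[m$r_index]
    else if (is.numeric(m) && length(m) == 1L) m
    else stop_param("`%s` must be an mcp or a single R amplitude in mV", name)
  }
  a_t <- amp(test_mcp, "test_mcp")
  a_r <- amp(reference_mcp, "reference_mcp")
  structure(list(test_mv = a_t, reference_mv = a_r,
                 delta_mv = abs(a_t - a_r)),
            class = "amplitude_delta")
}

#' @export
print.amplitude_delta <- function(x, ...) {
  cat(sprintf("<amplitude_delta> test %.4f mV vs reference %.4f mV: |diff| = %.4f mV\n",
              x$test_mv, x$reference_mv, x$delta_mv))
  invisible(x)
}
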