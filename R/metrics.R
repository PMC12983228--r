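#' Pearson correlation between reference and test waveforms
#'
#' Computed directly from its defining sum,
#' \deqn{R = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
#'   {\sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}},}
#' and clipped to \[-1, 1\] against floating-point rounding. R measures
#' shape agreement only: it is invariant to affine rescaling of either
#' waveform, which is why SNR and PRD accompany it.
#'
#' @param x reference waveform.
#' @param y test waveform, same length as `x` (>= 2).
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  check_pair(x, y, min_len = 2L)
  if (all(x == x[1]) || all(y == y[1])) {
    stop_param("correlation undefined for a constant vector")
  }
  dx <- x - mean(x); dy <- y - mean(y)
  r <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  max(-1, min(1, r))
}

#' Signal-to-noise ratio of a test waveform against its reference
#'
#' \deqn{SNR_{dB} = 10 \log_{10}\!\left(\frac{\sum_i x_i^2}
#'   {\sum_i (x_i - y_i)^2}\right),}
#' with the reference \eqn{x} as the useful signal and the channel
#' difference \eqn{x - y} as noise. An identical pair has zero error power
#' and returns `Inf` (treated as a sentinel and excluded from medians
#' downstream).
#'
#' @param x reference waveform (not all zero).
#' @param y test waveform, same length.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr_db <- function(x, y) {
  check_pair(x, y, min_len = 1L)
  if (all(x == 0)) stop_param("degenerate input: reference is all zero")
  err <- sum((x - y)^2)
  if (err == 0) return(Inf)
  10 * log10(sum(x^2) / err)
}

#' Percentage root-mean-square difference
#'
#' \deqn{PRD = 100 \sqrt{\frac{\sum_i (y_i - x_i)^2}{\sum_i x_i^2}},}
#' the channel error energy normalized by the reference energy, in percent.
#' Algebraically dual to the SNR: \eqn{PRD = 100 \cdot 10^{-SNR/20}}.
#'
#' @inheritParams snr_db
#' @return PRD in percent (>= 0).
#' @export
prd <- function(x, y) {
  check_pair(x, y, min_len = 1L)
  if (all(x == 0)) stop_param("degenerate input: reference is all zero")
  100 * sqrt(sum((y - x)^2) / sum(x^2))
}

check_pair <- function(x, y, min_len) {
  if (!is.numeric(x) || !is.numeric(y)) stop_param("waveforms must be numeric")
  if (length(x) != length(y)) stop_param("waveforms must have equal length")
  if (length(x) < min_len) stop_param("waveforms must have length >= %d", min_len)
  if (anyNA(x) || anyNA(y)) stop_param("waveforms must not contain NA")
}

#' Score a test/reference MCP pair per segment
#'
#' Computes the three quality indices (Pearson R, SNR in dB, PRD in %) for
#' the full median cardiac period and its P, QRS and T segments, slicing
#' both MCPs with identical indices. By convention x = reference slice,
#' y = test slice. Metrics run on the normalized MCPs by default; set
#' `use_normalized = FALSE` for raw-mV sensitivity analyses.
#'
#' @param test_mcp,reference_mcp `mcp` objects on the same time base.
#' @param windows a [segment_windows()].
#' @param use_normalized compute on normalized (default) or raw waveforms.
#' @return a tibble with one row per segment (`MCP`, `P`, `QRS`, `T`) and
#'   columns `segment`, `R`, `SNR_dB`, `PRD_pct`.
#' @export
score_pair <- function(test_mcp, reference_mcp, windows = segment_windows(),
                       use_normalized = TRUE) {
  if (length(test_mcp$raw) != length(reference_mcp$raw)) {
    stop_param("test and reference MCPs must have equal length")
  }
  y_all <- slice_segments(test_mcp, windows, use_normalized)
  x_all <- slice_segments(reference_mcp, windows, use_normalized)
  rows <- lapply(names(x_all), function(seg) {
    x <- x_all[[seg]]; y <- y_all[[seg]]
    tibble::tibble(segment = seg,
                   R = pearson_r(x, y),
                   SNR_dB = snr_db(x, y),
                   PRD_pct = prd(x, y))
  })
  dplyr::bind_rows(rows)
}
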