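#' Parametric five-wave beat template
#'
#' A beat is modelled as a sum of five Gaussians, one per ECG wave
#' (P, Q, R, S, T), each described by a signed amplitude in mV, a centre
#' offset relative to the R peak in ms, and a Gaussian width (standard
#' deviation) in ms. This parametric form gives exact ground truth for wave
#' positions and amplitudes, which downstream detector and
#' amplitude-difference tests rely on.
#'
#' Defaults approximate a normal-morphology precordial lead at ~1 mV R
#' amplitude.
#'
#' @param amplitude_mv named numeric (P, Q, R, S, T): signed wave amplitudes
#'   in mV. R must be positive; Q and S must be non-positive.
#' @param center_ms named numeric: wave centres relative to R in ms
#'   (|offset| <= 450).
#' @param width_ms named numeric: Gaussian widths in ms, all positive.
#' @return a `beat_template` object.
#' @export
#' @examples
#' tpl <- beat_template()
#' beat <- generate_beat(tpl, rate = 500)
#' length(beat) # 350 samples = 700 ms at 500 Hz
beat_template <- function(amplitude_mv = c(P = 0.15, Q = -0.10, R = 1.00,
                                           S = -0.25, T = 0.35),
                          center_ms = c(P = -160, Q = -28, R = 0,
                                        S = 30, T = 250),
                          width_ms = c(P = 25, Q = 9, R = 12,
                                      S = 10, T = 55)) {
  waves <- c("P", "Q", "R", "S", "T")
  for (arg in list(amplitude_mv, center_ms, width_ms)) {
    if (!is.numeric(arg) || !setequal(names(arg), waves)) {
      stop_param("beat_template arguments must be numeric vectors named P, Q, R, S, T")
    }
  }
  amplitude_mv <- amplitude_mv[waves]
  center_ms <- center_ms[waves]
  width_ms <- width_ms[waves]
  if (!(amplitude_mv[["R"]] > 0)) stop_param("R amplitude must be > 0")
  if (amplitude_mv[["Q"]] > 0 || amplitude_mv[["S"]] > 0) {
    stop_param("Q and S amplitudes must be <= 0")
  }
  if (any(abs(center_ms) > 450)) stop_param("wave centres must satisfy |offset| <= 450 ms")
  if (any(width_ms <= 0)) stop_param("wave widths must be > 0")
  structure(list(amplitude_mv = amplitude_mv, center_ms = center_ms,
                 width_ms = width_ms),
            class = "beat_template")
}

#' @export
print.beat_template <- function(x, ...) {
  cat("<beat_template>\n")
  print(data.frame(amplitude_mV = x$amplitude_mv, center_ms = x$center_ms,
                   width_ms = x$width_ms))
  invisible(x)
}

#' Synthetic record configuration
#'
#' Describes one synthetic ECG channel before electrode distortion: duration,
#' sampling rate, heart rate and its beat-to-beat jitter, and the three
#' additive artifact components observed on surface ECG — slow baseline
#' (zero-line) drift, 50 Hz powerline hum, and broadband white noise.
#'
#' @param duration_s record duration in seconds (> 0).
#' @param rate sampling rate in Hz (> 200).
#' @param hr_bpm mean heart rate in beats per minute, in [30, 220].
#' @param rr_jitter_frac beat-to-beat RR jitter as a fraction of the mean RR
#'   (truncated normal, +-3 sd).
#' @param drift_mv baseline-drift amplitude in mV (>= 0).
#' @param drift_hz baseline-drift frequency in Hz.
#' @param powerline_mv 50 Hz hum amplitude in mV (>= 0).
#' @param noise_sd_mv white-noise standard deviation in mV (>= 0).
#' @param seed integer seed driving all randomness of [generate_record()].
#' @return a `record_config` object.
#' @export
record_config <- function(duration_s = 30, rate = 500, hr_bpm = 60,
                          rr_jitter_frac = 0, drift_mv = 0.15,
                          drift_hz = 0.3, powerline_mv = 0.05,
                          noise_sd_mv = 0.02, seed = 1L) {
  assert_scalar_num(duration_s, "duration_s", lower = 1e-9)
  assert_scalar_num(rate, "rate")
  if (rate <= 200) stop_param("rate must exceed 200 Hz (2 x the 100 Hz band edge)")
  assert_scalar_num(hr_bpm, "hr_bpm", lower = 30, upper = 220)
  assert_scalar_num(rr_jitter_frac, "rr_jitter_frac", lower = 0)
  assert_scalar_num(drift_mv, "drift_mv", lower = 0)
  assert_scalar_num(drift_hz, "drift_hz", lower = 0)
  assert_scalar_num(powerline_mv, "powerline_mv", lower = 0)
  assert_scalar_num(noise_sd_mv, "noise_sd_mv", lower = 0)
  structure(list(duration_s = duration_s, rate = rate, hr_bpm = hr_bpm,
                 rr_jitter_frac = rr_jitter_frac, drift_mv = drift_mv,
                 drift_hz = drift_hz, powerline_mv = powerline_mv,
                 noise_sd_mv = noise_sd_mv, seed = seed),
            class = "record_config")
}

#' Electrode distortion model
#'
#' Describes how a test electrode (for example a dry textile electrode)
#' degrades the signal relative to the reference channel: per-wave amplitude
#' scaling of the clean beat component (a reduced R or exaggerated S/T is a
#' typical dry-electrode signature), stronger baseline drift, extra broadband
#' noise, intermittent motion-artifact bursts, and a constant channel lag.
#'
#' @param wave_scale named numeric (P, Q, R, S, T) of positive amplitude scale
#'   factors applied to the clean beat component; 1 means unchanged.
#' @param extra_drift_mv additional baseline-drift amplitude (mV, >= 0).
#' @param extra_drift_hz frequency of the additional drift (Hz).
#' @param extra_noise_sd_mv additional white-noise standard deviation (mV).
#' @param burst_rate_per_min expected motion-artifact bursts per minute.
#' @param burst_mv peak amplitude of each motion burst (mV).
#' @param lag_ms constant channel lag in ms (test relative to reference).
#' @return an `electrode_distortion` object.
#' @export
electrode_distortion <- function(wave_scale = c(P = 1, Q = 1, R = 1, S = 1, T = 1),
                                 extra_drift_mv = 0, extra_drift_hz = 0.2,
                                 extra_noise_sd_mv = 0,
                                 burst_rate_per_min = 0, burst_mv = 0,
                                 lag_ms = 0) {
  waves <- c("P", "Q", "R", "S", "T")
  if (!is.numeric(wave_scale) || !setequal(names(wave_scale), waves)) {
    stop_param("wave_scale must be a numeric vector named P, Q, R, S, T")
  }
  wave_scale <- wave_scale[waves]
  if (any(wave_scale <= 0)) stop_param("wave_scale factors must be > 0")
  assert_scalar_num(extra_drift_mv, "extra_drift_mv", lower = 0)
  assert_scalar_num(extra_drift_hz, "extra_drift_hz", lower = 0)
  assert_scalar_num(extra_noise_sd_mv, "extra_noise_sd_mv", lower = 0)
  assert_scalar_num(burst_rate_per_min, "burst_rate_per_min", lower = 0)
  assert_scalar_num(burst_mv, "burst_mv", lower = 0)
  assert_scalar_num(lag_ms, "lag_ms")
  structure(list(wave_scale = wave_scale, extra_drift_mv = extra_drift_mv,
                 extra_drift_hz = extra_drift_hz,
                 extra_noise_sd_mv = extra_noise_sd_mv,
                 burst_rate_per_min = burst_rate_per_min, burst_mv = burst_mv,
                 lag_ms = lag_ms),
            class = "electrode_distortion")
}

# Render the sum-of-Gaussians beat component over the whole record.
# centers_ms are R-peak times. Each wave is evaluated where it is
# non-negligible (+-6 widths) for speed.
render_beat_component <- function(centers_ms, template, n, rate) {
  clean <- numeric(n)
  t_ms <- (seq_len(n) - 1) / rate * 1000
  for (ctr in centers_ms) {
    for (w in c("P", "Q", "R", "S", "T")) {
      a <- template$amplitude_mv[[w]]
      if (a == 0) next
      mu <- ctr + template$center_ms[[w]]
      sdv <- template$width_ms[[w]]
      lo <- max(1L, ms_to_samples(mu - 6 * sdv, rate) + 1L)
      hi <- min(n, ms_to_samples(mu + 6 * sdv, rate) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      clean[idx] <- clean[idx] + a * exp(-((t_ms[idx] - mu)^2) / (2 * sdv^2))
    }
  }
  clean
}

# Per-sample class labels (0 background, 1 Q, 2 R, 3 S) within +-10 ms of
# each wave centre. R is written last so it wins any overlap.
render_label_mask <- function(centers_ms, template, n, rate, halfwidth_ms = 10) {
  labels <- integer(n)
  mark <- function(offsets_ms, code) {
    for (ctr in centers_ms) {
      mu <- ctr + offsets_ms
      lo <- max(1L, ms_to_samples(mu - halfwidth_ms, rate) + 1L)
      hi <- min(n, ms_to_samples(mu + halfwidth_ms, rate) + 1L)
      if (lo <= hi) labels[lo:hi] <<- code
    }
  }
  mark(template$center_ms[["Q"]], 1L)
  mark(template$center_ms[["S"]], 3L)
  mark(template$center_ms[["R"]], 2L)
  labels
}

#' Generate one beat waveform
#'
#' Evaluates the five-Gaussian beat template over a 700 ms window
#' (250 ms before to 450 ms after the R centre), the same window later used
#' for cardiac-period extraction.
#'
#' @param template a [beat_template()].
#' @param rate sampling rate in Hz.
#' @return numeric waveform of length `round(0.7 * rate)`; the R centre falls
#'   at (1-based) index `round(0.25 * rate) + 1`.
#' @export
generate_beat <- function(template, rate = 500) {
  if (!inherits(template, "beat_template")) stop_param("`template` must be a beat_template")
  assert_scalar_num(rate, "rate", lower = 1)
  n <- as.integer(round(0.7 * rate))
  t_ms <- (seq_len(n) - 1) / rate * 1000 - 250
  out <- numeric(n)
  for (w in c("P", "Q", "R", "S", "T")) {
    a <- template$amplitude_mv[[w]]
    if (a == 0) next
    out <- out + a * exp(-((t_ms - template$center_ms[[w]])^2) /
                           (2 * template$width_ms[[w]]^2))
  }
  out
}

#' Generate a labelled synthetic ECG record
#'
#' Places beats at jittered RR intervals around the configured heart rate and
#' adds baseline drift, 50 Hz powerline hum and white noise. Ground-truth
#' R-peak sample indices, a per-sample Q/R/S label mask and true RR intervals
#' are recorded from the clean beat component before any noise is added.
#' All randomness is drawn from one generator seeded with `config$seed`;
#' identical configurations give bit-identical records.
#'
#' @param config a [record_config()].
#' @param template a [beat_template()].
#' @return a `labeled_record`: list with `signal` (mV), `rate`, `r_idx`
#'   (1-based truth R sample indices), `labels` (0 background / 1 Q / 2 R /
#'   3 S), `rr_ms` (true RR intervals), and the additive `components`
#'   (clean, drift, hum, noise) kept for oracle checks and electrode
#'   distortion.
#' @export
generate_record <- function(config = record_config(), template = beat_template()) {
  if (!inherits(config, "record_config")) stop_param("`config` must be a record_config")
  if (!inherits(template, "beat_template")) stop_param("`template` must be a beat_template")
  rate <- config$rate
  n <- as.integer(round(config$duration_s * rate))
  rr_mean <- 60000 / config$hr_bpm

  with_local_seed(config$seed, {
    # beat centres: first R half an RR into the record, then jittered RR steps
    centers <- numeric(0)
    t <- rr_mean / 2
    max_ms <- config$duration_s * 1000 - 450  # full beat must fit
    while (t <= max_ms) {
      centers <- c(centers, t)
      z <- rnorm(1)
      z <- max(min(z, 3), -3)
      t <- t + rr_mean * (1 + config$rr_jitter_frac * z)
    }
    if (length(centers) == 0L) stop_param("record too short to contain one beat")

    clean <- render_beat_component(centers, template, n, rate)
    labels <- render_label_mask(centers, template, n, rate)
    r_idx <- ms_to_samples(centers, rate) + 1L

    tt <- (seq_len(n) - 1) / rate
    drift_phase <- runif(1, 0, 2 * pi)
    hum_phase <- runif(1, 0, 2 * pi)
    drift <- config$drift_mv * sin(2 * pi * config$drift_hz * tt + drift_phase)
    hum <- config$powerline_mv * sin(2 * pi * 50 * tt + hum_phase)
    noise <- if (config$noise_sd_mv > 0) rnorm(n, sd = config$noise_sd_mv) else numeric(n)

    structure(list(
      signal = clean + drift + hum + noise,
      rate = rate,
      r_idx = r_idx,
      labels = labels,
      rr_ms = diff(centers),
      beat_centers_ms = centers,
      components = list(clean = clean, drift = drift, hum = hum, noise = noise),
      template = template,
      config = config
    ), class = "labeled_record")
  })
}

#' @export
print.labeled_record <- function(x, ...) {
  cat(sprintf("<labeled_record> %.1f s @ %g Hz, %d beats\n",
              length(x$signal) / x$rate, x$rate, length(x$r_idx)))
  invisible(x)
}

#' Apply an electrode distortion to a labelled record
#'
#' Produces the test channel of a simultaneous recording: the clean beat
#' component is re-rendered with per-wave amplitude scaling, the original
#' drift/hum/noise components are kept (the two electrodes see the same
#' heart and the same mains field), and electrode-specific extra drift,
#' extra noise and motion bursts — drawn independently of the source
#' record's randomness via `seed` — are added. A constant channel lag shifts
#' signal and annotations together.
#'
#' @param record a `labeled_record` from [generate_record()].
#' @param distortion an [electrode_distortion()].
#' @param seed integer seed for the distortion's own randomness.
#' @return a `labeled_record` for the test channel, sharing truth annotations
#'   (lag-shifted).
#' @export
apply_electrode <- function(record, distortion = electrode_distortion(),
                            seed = 1L) {
  if (!inherits(record, "labeled_record")) stop_param("`record` must be a labeled_record")
  if (!inherits(distortion, "electrode_distortion")) {
    stop_param("`distortion` must be an electrode_distortion")
  }
  rate <- record$rate
  n <- length(record$signal)

  tpl <- record$template
  tpl$amplitude_mv <- tpl$amplitude_mv * distortion$wave_scale[names(tpl$amplitude_mv)]
  # scaling can flip none of the sign constraints (factors > 0), so the
  # scaled template is still valid
  clean <- render_beat_component(record$beat_centers_ms, tpl, n, rate)

  with_local_seed(seed, {
    tt <- (seq_len(n) - 1) / rate
    extra <- numeric(n)
    if (distortion$extra_drift_mv > 0) {
      ph <- runif(1, 0, 2 * pi)
      extra <- extra + distortion$extra_drift_mv *
        sin(2 * pi * distortion$extra_drift_hz * tt + ph)
    }
    if (distortion$extra_noise_sd_mv > 0) {
      extra <- extra + rnorm(n, sd = distortion$extra_noise_sd_mv)
    }
    if (distortion$burst_rate_per_min > 0 && distortion$burst_mv > 0) {
      duration_min <- n / rate / 60
      n_bursts <- rpois(1, distortion$burst_rate_per_min * duration_min)
      for (b in seq_len(n_bursts)) {
        len <- as.integer(round(0.5 * rate))     # 500 ms transients
        start <- sample.int(max(1L, n - len), 1L)
        walk <- cumsum(rnorm(len))
        walk <- walk / max(abs(walk)) * distortion$burst_mv
        win <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))  # Hann taper
        idx <- start:(start + len - 1L)
        extra[idx] <- extra[idx] + walk * win
      }
    }

    sig <- clean + record$components$drift + record$components$hum +
      record$components$noise + extra

    lag_n <- ms_to_samples(distortion$lag_ms, rate)
    if (lag_n != 0) {
      if (lag_n > 0) {
        sig <- c(rep(sig[1], lag_n), sig[seq_len(n - lag_n)])
      } else {
        sig <- c(sig[(-lag_n + 1):n], rep(sig[n], -lag_n))
      }
    }
    r_idx <- record$r_idx + lag_n
    keep <- r_idx >= 1L & r_idx <= n
    labels <- integer(n)
    src <- seq_len(n) - lag_n
    ok <- src >= 1L & src <= n
    labels[ok] <- record$labels[src[ok]]

    out <- record
    out$signal <- sig
    out$r_idx <- r_idx[keep]
    out$labels <- labels
    out$rr_ms <- record$rr_ms
    out$beat_centers_ms <- record$beat_centers_ms + distortion$lag_ms
    out$components <- list(clean = clean, drift = record$components$drift,
                           hum = record$components$hum,
                           noise = record$components$noise, extra = extra)
    out$template <- tpl
    out$distortion <- distortion
    out
  })
}

#' Generate a morphologically varied training corpus
#'
#' Convenience generator for detector training: each record draws its own
#' beat morphology (R amplitude 0.5–1.5 mV, S depth up to 1.5 x the R
#' amplitude in a fraction of records, jittered wave widths and offsets),
#' heart rate (50–90 bpm), RR jitter and artifact levels, so the trained
#' segmentation model sees both normal beats and the low-R/deep-S
#' morphology that defeats amplitude-threshold detectors. All draws come
#' from one generator seeded with `seed`.
#'
#' @param n number of records.
#' @param duration_s record duration in seconds.
#' @param rate sampling rate in Hz.
#' @param seed master seed.
#' @return list of `labeled_record`s.
#' @export
training_records <- function(n = 20L, duration_s = 30, rate = 500, seed = 1L) {
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      r_amp <- runif(1, 0.5, 1.5)
      deep_s <- i %% 4 == 0  # every fourth record: S deeper than R
      s_amp <- if (deep_s) -r_amp * runif(1, 1.1, 1.5) else -r_amp * runif(1, 0.1, 0.4)
      tpl <- beat_template(
        amplitude_mv = c(P = runif(1, 0.05, 0.25), Q = -runif(1, 0.03, 0.15),
                         R = r_amp, S = s_amp, T = runif(1, 0.1, 0.5)),
        center_ms = c(P = -160 + runif(1, -20, 20), Q = -28 + runif(1, -6, 6),
                      R = 0, S = 30 + runif(1, -5, 15), T = 250 + runif(1, -30, 30)),
        width_ms = c(P = 25 * runif(1, 0.8, 1.2), Q = 9 * runif(1, 0.8, 1.2),
                    R = 12 * runif(1, 0.8, 1.2), S = 10 * runif(1, 0.8, 1.2),
                    T = 55 * runif(1, 0.8, 1.2)))
      cfg <- record_config(
        duration_s = duration_s, rate = rate,
        hr_bpm = runif(1, 50, 90), rr_jitter_frac = runif(1, 0, 0.08),
        drift_mv = runif(1, 0, 0.3), drift_hz = runif(1, 0.1, 0.5),
        powerline_mv = runif(1, 0, 0.1), noise_sd_mv = runif(1, 0.005, 0.05),
        seed = sample.int(1e6, 1))
      generate_record(cfg, tpl)
    })
  })
}

#' Build a reference/test pair at a requested SNR
#'
#' Adds white noise to a copy of `record`, with the noise vector rescaled in
#' closed form so that the SNR definition
#' \eqn{10 \log_{10}(\sum x_i^2 / \sum (x_i - y_i)^2)} evaluated on the
#' emitted pair equals `target_snr_db` exactly: the realized noise vector is
#' scaled to energy \eqn{\sum x^2 \cdot 10^{-SNR/10}}.
#'
#' @param record a `labeled_record` (the reference channel).
#' @param target_snr_db requested SNR in dB; `Inf` returns an identical copy.
#' @param seed integer seed for the noise draw.
#' @return list with elements `reference` and `test` (both `labeled_record`).
#' @export
requested_snr_pair <- function(record, target_snr_db, seed = 1L) {
  if (!inherits(record, "labeled_record")) stop_param("`record` must be a labeled_record")
  assert_scalar_num(target_snr_db, "target_snr_db", allow_inf = TRUE)
  x <- record$signal
  if (all(x == 0)) stop_param("degenerate input: reference signal is all zero")
  test <- record
  if (!is.infinite(target_snr_db)) {
    noise <- with_local_seed(seed, rnorm(length(x)))
    target_energy <- sum(x^2) * 10^(-target_snr_db / 10)
    noise <- noise * sqrt(target_energy / sum(noise^2))
    test$signal <- x + noise
  }
  list(reference = record, test = test)
}
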