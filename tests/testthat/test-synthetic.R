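test_that("generate_beat matches direct Gaussian summation", {
  # zero template: amplitudes may not all be zero by construction (R > 0),
  # so test the single-wave case and the full oracle instead
  tpl_r <- beat_template(amplitude_mv = c(P = 0, Q = 0, R = 1, S = 0, T = 0))
  b <- generate_beat(tpl_r, 500)
  expect_length(b, 350L)
  expect_equal(which.max(b), 126L)  # R centre, 250 ms in (0-based index 125)
  expect_equal(max(b), 1.0, tolerance = 1e-12)

  # brute-force oracle: sum the five Gaussians sample by sample
  tpl <- beat_template()
  b2 <- generate_beat(tpl, 500)
  t_ms <- (0:349) / 500 * 1000 - 250
  oracle <- rowSums(sapply(c("P", "Q", "R", "S", "T"), function(w) {
    tpl$amplitude_mv[[w]] *
      exp(-(t_ms - tpl$center_ms[[w]])^2 / (2 * tpl$width_ms[[w]]^2))
  }))
  expect_equal(b2, oracle, tolerance = 1e-12)
  # overlapping Q/S pull the peak slightly below the R amplitude
  expect_lt(abs(max(b2) - tpl$amplitude_mv[["R"]]) / tpl$amplitude_mv[["R"]], 0.01)
})

test_that("beat template invariants are enforced", {
  expect_error(beat_template(amplitude_mv = c(P = 0.1, Q = -0.1, R = -1,
                                              S = -0.2, T = 0.3)), "R amplitude")
  expect_error(beat_template(amplitude_mv = c(P = 0.1, Q = 0.1, R = 1,
                                              S = -0.2, T = 0.3)), "Q and S")
  expect_error(beat_template(width_ms = c(P = 25, Q = 0, R = 12, S = 10, T = 55)),
               "widths")
  expect_error(beat_template(center_ms = c(P = -500, Q = -28, R = 0, S = 30,
                                          T = 250)), "450")
})

test_that("noise-free 60 bpm record has exact 1000 ms spacing and is deterministic", {
  rec <- generate_record(clean_config(30, seed = 1L))
  expect_length(rec$r_idx, 30L)
  expect_true(all(rec$rr_ms == 1000))
  expect_true(all(diff(rec$r_idx) == 500L))
  rec2 <- generate_record(clean_config(30, seed = 1L))
  expect_identical(rec$signal, rec2$signal)
  expect_identical(rec$r_idx, rec2$r_idx)
  # different seed changes the noise draw
  cfg3 <- record_config(duration_s = 30, seed = 3L)
  expect_false(identical(generate_record(cfg3)$signal,
                         generate_record(record_config(duration_s = 30,
                                                       seed = 4L))$signal))
})

test_that("jittered RR intervals average to the configured heart rate", {
  cfg <- record_config(duration_s = 300, rr_jitter_frac = 0.05, seed = 7L)
  rec <- generate_record(cfg)
  expect_lt(abs(mean(rec$rr_ms) - 1000) / 1000, 0.02)
  # oracle: sample the generating RR distribution directly
  rr <- with_seed_for_test(7L, {
    z <- pmax(pmin(rnorm(1e5), 3), -3)
    1000 * (1 + 0.05 * z)
  })
  expect_lt(abs(mean(rec$rr_ms) - mean(rr)), 0.02 * 1000)
})

test_that("label mask is consistent with the clean beat component", {
  rec <- generate_record(record_config(duration_s = 30, rr_jitter_frac = 0.05,
                                       seed = 2L))
  expect_length(rec$labels, length(rec$signal))
  expect_true(all(rec$labels[rec$r_idx] == 2L))
  expect_true(all(diff(rec$r_idx) > 0))
  # every truth R index is the argmax of the clean component within +-1 sample
  ok <- vapply(rec$r_idx, function(i) {
    lo <- max(1L, i - 60L); hi <- min(length(rec$signal), i + 60L)
    abs((lo + which.max(rec$components$clean[lo:hi]) - 1L) - i) <= 1L
  }, logical(1))
  expect_true(all(ok))
})

test_that("identity electrode distortion returns the input signal", {
  rec <- generate_record(record_config(duration_s = 20, seed = 5L))
  out <- apply_electrode(rec, electrode_distortion(), seed = 9L)
  expect_equal(out$signal, rec$signal, tolerance = 1e-12)
  expect_identical(out$r_idx, rec$r_idx)
})

test_that("R-wave scaling halves beat peaks (regeneration oracle)", {
  rec <- generate_record(clean_config(20, seed = 6L))
  half <- apply_electrode(rec, electrode_distortion(
    wave_scale = c(P = 1, Q = 1, R = 0.5, S = 1, T = 1)), seed = 1L)
  # oracle: regenerate with halved R amplitude in the template
  tpl <- beat_template()
  tpl$amplitude_mv[["R"]] <- 0.5
  oracle <- generate_record(clean_config(20, seed = 6L), tpl)
  expect_equal(half$signal, oracle$signal, tolerance = 1e-10)
  for (i in rec$r_idx) {
    w <- (i - 10):(i + 10)
    expect_equal(max(half$signal[w]) / max(rec$signal[w]), 0.5, tolerance = 0.02)
  }
})

test_that("extra electrode noise injects the requested power", {
  rec <- generate_record(clean_config(60, seed = 8L))
  noisy <- apply_electrode(rec, electrode_distortion(extra_noise_sd_mv = 0.1),
                           seed = 3L)
  mse <- mean((noisy$signal - rec$signal)^2)
  expect_lt(abs(mse - 0.01) / 0.01, 0.10)
})

test_that("channel lag shifts annotations with the signal", {
  rec <- generate_record(clean_config(20, seed = 10L))
  lag <- apply_electrode(rec, electrode_distortion(lag_ms = 20), seed = 1L)
  expect_identical(lag$r_idx, rec$r_idx + 10L)
  expect_true(all(lag$labels[lag$r_idx] == 2L))
})

test_that("requested_snr_pair hits the target SNR", {
  rec <- generate_record(record_config(duration_s = 60, seed = 2L))
  for (target in c(0, 10, 20, 30)) {
    pr <- requested_snr_pair(rec, target, seed = 3L)
    expect_lt(abs(snr_db(pr$reference$signal, pr$test$signal) - target), 0.2)
  }
  # mean absolute error over 20 seeds
  errs <- vapply(1:20, function(s) {
    pr <- requested_snr_pair(rec, 20, seed = s)
    abs(snr_db(pr$reference$signal, pr$test$signal) - 20)
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
  # 0 dB means equal noise and signal power
  pr0 <- requested_snr_pair(rec, 0, seed = 4L)
  noise_p <- sum((pr0$test$signal - pr0$reference$signal)^2)
  expect_lt(abs(noise_p - sum(rec$signal^2)) / sum(rec$signal^2), 0.02)
  # infinite target: identical channels
  pri <- requested_snr_pair(rec, Inf, seed = 5L)
  expect_identical(pri$test$signal, pri$reference$signal)
  # degenerate reference
  zero <- rec; zero$signal <- rep(0, length(rec$signal))
  expect_error(requested_snr_pair(zero, 20), "all zero")
})

test_that("SNR of a pair strictly decreases as extra noise grows", {
  rec <- generate_record(clean_config(30, seed = 12L))
  snrs <- vapply(c(0.01, 0.02, 0.05, 0.1, 0.2), function(s) {
    noisy <- apply_electrode(rec, electrode_distortion(extra_noise_sd_mv = s),
                             seed = 7L)
    snr_db(rec$signal, noisy$signal)
  }, numeric(1))
  expect_true(all(diff(snrs) < 0))
})
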