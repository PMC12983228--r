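test_that("period windows are 350 samples at 500 Hz with R at local index 126", {
  sig <- rnorm(15000)
  per <- extract_periods(sig, 500, c(1000L, 2000L, 3000L))
  expect_equal(dim(per$beats), c(3L, 350L))
  expect_equal(per$r_local, 126L)   # 0-based 125
  expect_equal(per$beats[1, ], sig[875:1224])  # [R-125, R+225) in samples
  expect_equal(per$beats[1, 126], sig[1000])   # R sample at the local R index
  expect_equal(per$n_skipped, 0L)
})

test_that("edge beats are skipped and counted", {
  sig <- rnorm(2000)
  per <- extract_periods(sig, 500, c(100L, 1000L, 1990L))
  expect_equal(nrow(per$beats), 1L)
  expect_equal(per$n_skipped, 2L)
  expect_equal(per$source_idx, 1000L)
})

test_that("window arithmetic is rate-independent in milliseconds", {
  for (rate in c(250, 360, 500, 1000)) {
    sig <- rnorm(10 * rate)
    per <- extract_periods(sig, rate, as.integer(5 * rate))
    expect_equal(ncol(per$beats), round(0.7 * rate))
    expect_equal(per$r_local, round(0.25 * rate) + 1L)
  }
})

test_that("MCP is the sample-wise median and is outlier-robust", {
  # identical beats: median equals any beat
  beat <- generate_beat(beat_template(), 500)
  sig <- rep(0, 5000)
  idx <- c(1000L, 2000L, 3000L)
  for (i in idx) sig[(i - 125):(i + 224)] <- beat
  per <- extract_periods(sig, 500, idx)
  mcp <- compute_mcp(per)
  expect_equal(mcp$raw, beat, tolerance = 1e-12)
  # {1, 1, 9} at one sample -> median 1
  per$beats[3, 200] <- 9
  per$beats[1:2, 200] <- 1
  expect_equal(compute_mcp(per)$raw[200], 1)
  # corrupting floor((n-1)/2) of n beats does not change the median
  per2 <- extract_periods(sig, 500, idx)
  base <- compute_mcp(per2)$raw[150]
  per2$beats[1, 150] <- per2$beats[1, 150] + 100
  expect_equal(compute_mcp(per2)$raw[150], base)
})

test_that("normalization is min-max to [0,1] and idempotent", {
  # raw median with min -0.2 and max 1.0 -> (x + 0.2) / 1.2
  beats <- matrix(c(-0.2, 0.4, 1.0), 1, 3)
  per <- structure(list(beats = beats, rate = 500, pre_ms = 250, post_ms = 450,
                        r_local = 3L, source_idx = 1L, n_skipped = 0L),
                   class = "cardiac_period_set")
  mcp <- compute_mcp(per)
  expect_equal(mcp$normalized, (c(-0.2, 0.4, 1.0) + 0.2) / 1.2, tolerance = 1e-12)
  expect_equal(min(mcp$normalized), 0)
  expect_equal(max(mcp$normalized), 1)
  # renormalizing an already-normalized waveform changes nothing
  per$beats <- matrix(mcp$normalized, 1)
  expect_equal(compute_mcp(per)$normalized, mcp$normalized, tolerance = 1e-12)
  # constant median is degenerate
  per$beats <- matrix(1, 1, 3)
  expect_error(compute_mcp(per), "degenerate")
})

test_that("segment slicing has the contracted sample counts at 500 Hz", {
  rec <- generate_record(record_config(duration_s = 30, seed = 4L))
  mcp <- compute_mcp(extract_periods(rec$signal, 500, rec$r_idx))
  segs <- slice_segments(mcp)
  expect_length(segs$MCP, 350L)
  expect_length(segs$P, 95L)
  expect_length(segs$QRS, 60L)
  expect_length(segs$T, 165L)
  # full-window segment equals the MCP itself
  full <- slice_segments(mcp, segment_windows(p = c(-250, -60), qrs = c(-60, 60),
                                              t = c(120, 450)))
  expect_identical(full$MCP, mcp$normalized)
  # shifting the T start by +10 ms drops exactly 5 samples at 500 Hz
  shifted <- slice_segments(mcp, segment_windows(t = c(130, 450)))
  expect_length(shifted$T, 160L)
  # invalid windows are rejected
  expect_error(segment_windows(qrs = c(10, 60)), "contain the R-peak")
  expect_error(segment_windows(p = c(-250, -50), qrs = c(-60, 60)), "precede")
  expect_error(slice_segments(mcp, segment_windows(t = c(120, 460))), "outside")
})

test_that("amplitude differences reproduce the reported synthetic-study values", {
  # textile-vs-reference R amplitudes measured on raw MCPs
  expect_equal(amplitude_difference(1.0605, 1.0631)$delta_mv, 0.0026,
               tolerance = 1e-12)
  expect_equal(amplitude_difference(1.0671, 1.0631)$delta_mv, 0.0040,
               tolerance = 1e-12)
  expect_equal(amplitude_difference(1.0631, 1.0631)$delta_mv, 0)
})

test_that("amplitude difference reads raw MCPs at the R index", {
  rec <- generate_record(clean_config(30, seed = 5L))
  scaled <- apply_electrode(rec, electrode_distortion(
    wave_scale = c(P = 1, Q = 1, R = 0.9, S = 1, T = 1)), seed = 1L)
  mcp_ref <- compute_mcp(extract_periods(rec$signal, 500, rec$r_idx))
  mcp_test <- compute_mcp(extract_periods(scaled$signal, 500, rec$r_idx))
  d <- amplitude_difference(mcp_test, mcp_ref)
  expect_equal(d$reference_mv, mcp_ref$raw[126])
  # a 10% R scaling shows up as ~0.1 x R amplitude difference
  expect_equal(d$delta_mv, 0.1 * mcp_ref$raw[126], tolerance = 0.02)
})
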