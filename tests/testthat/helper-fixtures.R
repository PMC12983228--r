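# Shared fixtures. The trained segmentation model is expensive, so it is
# built once per test run and reused by every test that needs it.

.fixtures <- new.env(parent = emptyenv())

with_seed_for_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

clean_config <- function(duration_s = 30, seed = 1L, ...) {
  record_config(duration_s = duration_s, rr_jitter_frac = 0, drift_mv = 0,
                powerline_mv = 0, noise_sd_mv = 0, seed = seed, ...)
}

# deep-S / low-R morphology that defeats amplitude-threshold detectors
deep_s_template <- function() {
  beat_template(amplitude_mv = c(P = 0.15, Q = -0.1, R = 0.6, S = -0.9, T = 0.35),
                center_ms = c(P = -160, Q = -28, R = 0, S = 40, T = 250),
                width_ms = c(P = 25, Q = 9, R = 12, S = 10, T = 55))
}

shared_segmenter <- function() {
  if (is.null(.fixtures$model)) {
    recs <- training_records(20, 30, seed = 11L)
    .fixtures$model <- train_segmenter(recs, seed = 42L)
  }
  .fixtures$model
}

# run the full detection chain (preprocess -> probabilities -> detect ->
# verify) on a labelled record and match against ground truth
detect_and_score <- function(record, model, tol_ms = 25) {
  pp <- preprocess_record(record)
  probs <- predict_probabilities(model, pp)
  peaks <- verify_by_correlation(pp, detect_rpeaks(pp, probs))
  detection_stats(record$r_idx, accepted_peaks(peaks), record$rate,
                  tol_ms = tol_ms)
}
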