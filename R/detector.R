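#' Detector configuration
#'
#' Tunables for the scalogram/segmentation R-peak detector.
#'
#' @param theta_r threshold on the R-class probability for candidate peaks,
#'   in (0, 1).
#' @param qs_window_ms context window (ms): a candidate R must have a Q-class
#'   probability maximum within this window before it and an S-class maximum
#'   within it after.
#' @param theta_qs minimum probability a Q/S local maximum must reach to
#'   count as support, in (0, 1).
#' @param refine_ms half-width (ms) of the window in which the R position is
#'   refined to the signal extremum of dominant polarity.
#' @param verify_halfwidth_ms half-width (ms) of the excerpt used for
#'   correlation verification.
#' @param rho_min minimum correlation against the median excerpt for a peak
#'   to be kept, in (0, 1).
#' @param min_rr_ms minimum RR interval (ms); closer candidates are merged.
#' @return a `detector_config` object.
#' @export
detector_config <- function(theta_r = 0.5, qs_window_ms = 100, theta_qs = 0.1,
                            refine_ms = 40, verify_halfwidth_ms = 150,
                            rho_min = 0.8, min_rr_ms = 250) {
  assert_scalar_num(theta_r, "theta_r", lower = 1e-9, upper = 1 - 1e-9)
  assert_scalar_num(qs_window_ms, "qs_window_ms", lower = 1e-9)
  assert_scalar_num(theta_qs, "theta_qs", lower = 1e-9, upper = 1 - 1e-9)
  assert_scalar_num(refine_ms, "refine_ms", lower = 1e-9)
  assert_scalar_num(verify_halfwidth_ms, "verify_halfwidth_ms", lower = 1e-9)
  assert_scalar_num(rho_min, "rho_min", lower = 1e-9, upper = 1 - 1e-9)
  assert_scalar_num(min_rr_ms, "min_rr_ms", lower = 1e-9)
  structure(list(theta_r = theta_r, qs_window_ms = qs_window_ms,
                 theta_qs = theta_qs, refine_ms = refine_ms,
                 verify_halfwidth_ms = verify_halfwidth_ms,
                 rho_min = rho_min, min_rr_ms = min_rr_ms),
            class = "detector_config")
}

new_rpeak_set <- function(idx, prob = rep(NA_real_, length(idx)),
                          verification_r = rep(NA_real_, length(idx)),
                          accepted = rep(TRUE, length(idx)),
                          rate = NA_real_, record_id = NA_character_,
                          verified = FALSE, warning_flag = FALSE) {
  o <- order(idx)
  structure(list(idx = as.integer(idx[o]), prob = prob[o],
                 verification_r = verification_r[o], accepted = accepted[o],
                 rate = rate, record_id = record_id, verified = verified,
                 warning_flag = warning_flag),
            class = "rpeak_set")
}

#' Construct an R-peak set
#'
#' Build an `rpeak_set` from known peak indices — e.g. external annotations
#' or constructed test cases — so it can flow through
#' [verify_by_correlation()] and [extract_periods()] like detector output.
#'
#' @param idx integer 1-based sample indices of the peaks.
#' @param rate sampling rate in Hz.
#' @param prob optional per-peak detection probabilities.
#' @param record_id optional record identifier.
#' @return an `rpeak_set` with all peaks accepted and unverified.
#' @export
rpeak_set <- function(idx, rate, prob = rep(NA_real_, length(idx)),
                      record_id = NA_character_) {
  new_rpeak_set(as.integer(idx), prob = prob, rate = rate,
                record_id = record_id)
}

#' Accepted R-peak indices of an rpeak_set
#' @param peaks an `rpeak_set`.
#' @return integer vector of accepted 1-based sample indices.
#' @export
accepted_peaks <- function(peaks) peaks$idx[peaks$accepted]

#' @export
print.rpeak_set <- function(x, ...) {
  cat(sprintf("<rpeak_set> %d peaks (%d accepted)%s\n", length(x$idx),
              sum(x$accepted), if (x$verified) ", verified" else ""))
  invisible(x)
}

# z-normalize each scale row of a magnitude block; constant rows become 0
znorm_rows <- function(m) {
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))
  sdv[sdv == 0] <- 1
  (m - mu) / sdv
}

# Analysis-window index ranges over n samples (fixed length, fractional
# overlap, last window right-aligned).
window_starts <- function(n, window, overlap) {
  step <- max(1L, as.integer(window * (1 - overlap)))
  starts <- seq(1L, max(1L, n - window + 1L), by = step)
  if (starts[length(starts)] + window - 1L < n) starts <- c(starts, n - window + 1L)
  unique(pmax(1L, starts))
}

# Per-sample features inside one analysis window: the scalogram column
# (z-normalized per scale within the window) plus the z-normalized signal
# at a set of signed time lags. The lags carry the polarity and the
# Q-before-R-before-S timing that the magnitude scalogram discards.
segmenter_features <- function(x, mag, idx, rate, lags_ms) {
  sc <- t(znorm_rows(mag[, idx, drop = FALSE]))
  xs <- x[idx]
  xs <- (xs - mean(xs)) / max(sd(xs), 1e-12)
  n <- length(idx)
  lagf <- vapply(lags_ms, function(L) {
    k <- ms_to_samples(L, rate)
    xs[pmin(pmax(seq_len(n) + k, 1L), n)]
  }, numeric(n))
  cbind(sc, lagf)
}

#' Train the Q/R/S segmentation model
#'
#' Trains the per-sample classifier behind the scalogram detector: each
#' sample of a record is represented by its column of the Morlet scalogram
#' (z-normalized per scale within an analysis window) and classified into
#' background, Q, R or S by a single-hidden-layer softmax network fitted
#' with class-weighted cross-entropy. Minority classes (Q, R, S) receive
#' inverse-frequency weights so the network is not dominated by background
#' samples; background samples are additionally subsampled for speed.
#' Training is deterministic given `seed`.
#'
#' @param records list of `labeled_record`s (>= 2) from [generate_record()].
#' @param n_scales scalogram scales used as features.
#' @param freq_range pseudo-frequency span (Hz) of the scalogram.
#' @param hidden hidden-layer size.
#' @param decay weight decay (the regularizer standing in for dropout in this
#'   small network).
#' @param maxit maximum optimizer iterations.
#' @param bg_ratio background samples kept per labelled (Q/R/S) sample.
#' @param window,overlap analysis-window length (samples) and fractional
#'   overlap used both here and at inference.
#' @param lags_ms signed time lags (ms) at which the normalized signal value
#'   is appended to each sample's scalogram-column features.
#' @param seed integer seed for initialization and subsampling.
#' @return a `qrs_segmenter` model handle.
#' @export
train_segmenter <- function(records, n_scales = 32L, freq_range = c(1, 45),
                            hidden = 16L, decay = 1e-4, maxit = 200L,
                            bg_ratio = 2, window = 2048L, overlap = 0.5,
                            lags_ms = seq(-40, 40, by = 10), seed = 1L) {
  if (!is.list(records) || length(records) < 2L) {
    stop_param("need at least 2 labelled records")
  }
  rate <- records[[1]]$rate
  feats <- list(); labs <- list()
  for (rec in records) {
    if (!inherits(rec, "labeled_record")) stop_param("records must be labeled_records")
    if (length(rec$labels) != length(rec$signal)) {
      stop_param("label mask length does not match signal length")
    }
    if (rec$rate != rate) stop_param("all records must share one sampling rate")
    sc <- cwt_scalogram(rec$signal, rate, n_scales = n_scales,
                        freq_range = freq_range)
    for (s in window_starts(length(rec$signal), window, overlap)) {
      idx <- s:min(length(rec$signal), s + window - 1L)
      feats[[length(feats) + 1L]] <- segmenter_features(rec$signal, sc$magnitude,
                                                        idx, rate, lags_ms)
      labs[[length(labs) + 1L]] <- rec$labels[idx]
    }
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)

  with_local_seed(seed, {
    lab_i <- which(y != 0L)
    bg_i <- which(y == 0L)
    n_bg <- min(length(bg_i), as.integer(ceiling(bg_ratio * length(lab_i))))
    keep <- c(lab_i, sample(bg_i, n_bg))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    yf <- factor(y, levels = 0:3, labels = c("bg", "Q", "R", "S"))
    counts <- table(yf)
    cw <- as.numeric(sum(counts) / (length(counts) * counts))
    names(cw) <- names(counts)
    w <- cw[as.character(yf)]
    fit <- nnet::nnet(X, nnet::class.ind(yf), size = hidden, softmax = TRUE,
                      decay = decay, maxit = maxit, weights = w,
                      MaxNWts = 100000L, trace = FALSE)
    structure(list(net = fit, rate = rate, n_scales = n_scales,
                   freq_range = freq_range, window = window,
                   overlap = overlap, lags_ms = lags_ms,
                   classes = c("bg", "Q", "R", "S"),
                   final_value = fit$value, seed = seed),
              class = "qrs_segmenter")
  })
}

#' @export
print.qrs_segmenter <- function(x, ...) {
  cat(sprintf("<qrs_segmenter> %d scalogram scales, %d hidden units, %g Hz\n",
              x$n_scales, x$net$n[2], x$rate))
  invisible(x)
}

#' Per-sample class probability series
#'
#' Runs the segmentation model over a whole record with overlapping analysis
#' windows (same length and overlap as at training) and averages the
#' probabilities where windows overlap. Every sample gets a probability for
#' each of background, Q, R and S; the four values sum to 1 (up to averaging
#' of simplex points, which stays on the simplex).
#'
#' @param model a `qrs_segmenter`.
#' @param record a `labeled_record`, [ecg_record()] or numeric vector.
#' @param rate sampling rate (required for a bare vector); must equal the
#'   model's training rate.
#' @return a `class_probabilities` matrix (n x 4, columns bg/Q/R/S) with the
#'   sampling rate as attribute.
#' @export
predict_probabilities <- function(model, record, rate = NULL) {
  if (!inherits(model, "qrs_segmenter")) stop_param("`model` must be a qrs_segmenter")
  x <- record_samples(record)
  r <- record_rate(record, rate)
  if (!isTRUE(all.equal(r, model$rate))) {
    stop_param("record rate %g Hz does not match model training rate %g Hz",
               r, model$rate)
  }
  sc <- cwt_scalogram(x, r, n_scales = model$n_scales,
                      freq_range = model$freq_range)
  n <- length(x)
  acc <- matrix(0, n, 4L)
  cnt <- numeric(n)
  for (s in window_starts(n, model$window, model$overlap)) {
    idx <- s:min(n, s + model$window - 1L)
    feats <- segmenter_features(x, sc$magnitude, idx, r, model$lags_ms)
    p <- predict(model$net, feats, type = "raw")
    acc[idx, ] <- acc[idx, ] + p
    cnt[idx] <- cnt[idx] + 1
  }
  probs <- acc / cnt
  colnames(probs) <- model$classes
  structure(probs, rate = r, class = c("class_probabilities", "matrix", "array"))
}

record_samples <- function(record) {
  if (inherits(record, "labeled_record")) record$signal
  else if (inherits(record, "ecg_record")) record$samples
  else if (is.numeric(record)) as.numeric(record)
  else stop_param("unsupported record type")
}

record_rate <- function(record, rate = NULL) {
  if (inherits(record, c("labeled_record", "ecg_record"))) record$rate
  else if (!is.null(rate)) rate
  else stop_param("`rate` is required for a bare numeric signal")
}

#' Detect R-peaks from class probability series
#'
#' Candidate R positions are local maxima of the R-class probability series
#' above `theta_r`. A candidate is kept only if a Q-class probability
#' maximum precedes it and an S-class probability maximum follows it within
#' the context window — the morphological constraint that an R peak must sit
#' between its Q and S waves. The R position is then refined to the signal
#' extremum of dominant polarity within the refinement window, and
#' candidates closer than the minimum RR are merged keeping the higher
#' R probability.
#'
#' @param record a `labeled_record`, [ecg_record()] or numeric vector.
#' @param probs a `class_probabilities` matrix aligned with the record.
#' @param config a [detector_config()].
#' @param rate sampling rate (bare vectors only).
#' @return an `rpeak_set` (unverified; see [verify_by_correlation()]).
#' @export
detect_rpeaks <- function(record, probs, config = detector_config(),
                          rate = NULL) {
  x <- record_samples(record)
  r <- record_rate(record, rate)
  if (nrow(probs) != length(x)) stop_param("probability series not aligned with record")
  p_r <- probs[, "R"]; p_q <- probs[, "Q"]; p_s <- probs[, "S"]

  cand <- local_maxima(p_r)
  cand <- cand[p_r[cand] > config$theta_r]
  q_max <- local_maxima(p_q); q_max <- q_max[p_q[q_max] >= config$theta_qs]
  s_max <- local_maxima(p_s); s_max <- s_max[p_s[s_max] >= config$theta_qs]

  win <- ms_to_samples(config$qs_window_ms, r)
  keep <- vapply(cand, function(i) {
    any(q_max >= i - win & q_max < i) && any(s_max > i & s_max <= i + win)
  }, logical(1))
  cand <- cand[keep]

  # refine to the signal extremum of dominant polarity; polarity is decided
  # once per record (sign of the median signal value at the probability
  # maxima) so a deep S wave inside the refinement window cannot capture
  # the fiducial point
  ref_w <- ms_to_samples(config$refine_ms, r)
  pol <- if (length(cand)) sign(median(x[cand])) else 1
  if (pol == 0) pol <- 1
  refined <- vapply(cand, function(i) {
    lo <- max(1L, i - ref_w); hi <- min(length(x), i + ref_w)
    lo + which.max(pol * x[lo:hi]) - 1L
  }, integer(1))
  pr <- p_r[cand]

  # de-duplicate refined collisions, then merge < min RR keeping higher prob
  if (length(refined) > 1L) {
    o <- order(refined, -pr)
    refined <- refined[o]; pr <- pr[o]
    dup <- duplicated(refined)
    refined <- refined[!dup]; pr <- pr[!dup]
    min_rr <- ms_to_samples(config$min_rr_ms, r)
    repeat {
      gaps <- diff(refined)
      j <- which(gaps < min_rr)
      if (length(j) == 0L) break
      j <- j[1]
      drop <- if (pr[j] >= pr[j + 1L]) j + 1L else j
      refined <- refined[-drop]; pr <- pr[-drop]
    }
  }
  new_rpeak_set(refined, prob = pr, rate = r)
}

#' Verify detected peaks by correlation against the median excerpt
#'
#' For each accepted peak a +-`verify_halfwidth_ms` excerpt is cut from the
#' signal; the sample-wise median of all excerpts forms a beat template, and
#' each excerpt's Pearson correlation against that template is computed.
#' Peaks with correlation below `rho_min` are rejected in a single pass;
#' the template and the reported per-peak correlations are then recomputed
#' once from the surviving peaks. With fewer than 3 accepted peaks the set
#' is passed through unchanged with a warning flag.
#'
#' @inheritParams detect_rpeaks
#' @param peaks an `rpeak_set`.
#' @return the `rpeak_set` with `verification_r` filled in and rejected
#'   peaks' `accepted` flag cleared; never more accepted peaks than before.
#' @export
verify_by_correlation <- function(record, peaks, config = detector_config(),
                                  rate = NULL) {
  x <- record_samples(record)
  r <- record_rate(record, rate)
  acc_i <- which(peaks$accepted)
  if (length(acc_i) < 3L) {
    peaks$warning_flag <- TRUE
    peaks$verified <- TRUE
    return(peaks)
  }
  hw <- ms_to_samples(config$verify_halfwidth_ms, r)
  excerpt <- function(i) {
    if (i - hw < 1L || i + hw > length(x)) return(NULL)
    x[(i - hw):(i + hw)]
  }
  exc <- lapply(peaks$idx[acc_i], excerpt)
  usable <- !vapply(exc, is.null, logical(1))
  if (sum(usable) < 3L) {
    peaks$warning_flag <- TRUE
    peaks$verified <- TRUE
    return(peaks)
  }
  m <- do.call(rbind, exc[usable])
  med <- apply(m, 2, median)
  cors <- apply(m, 1, function(e) safe_cor(e, med))
  reject <- cors < config$rho_min
  peaks$verification_r[acc_i[usable]] <- cors
  peaks$accepted[acc_i[usable][reject]] <- FALSE

  # recompute the template once from survivors and refresh reported scores
  surv <- acc_i[usable][!reject]
  if (length(surv) >= 2L) {
    m2 <- m[!reject, , drop = FALSE]
    med2 <- apply(m2, 2, median)
    peaks$verification_r[surv] <- apply(m2, 1, function(e) safe_cor(e, med2))
  }
  peaks$verified <- TRUE
  peaks
}

safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  pearson_r(b, a)
}

#' Pan-Tompkins comparator detector
#'
#' The classical QRS detection chain: 5–15 Hz band-pass, five-point
#' derivative, squaring, 150 ms moving-window integration, and adaptive
#' dual thresholds on the integrated waveform with RR-based search-back.
#' Fiducial marks are refined to the largest absolute signal excursion
#' nearby — the step that mislocates beats when the S wave is deeper than
#' the R wave is tall, the known failure mode this detector is kept around
#' to demonstrate.
#'
#' @param record a `labeled_record`, [ecg_record()] or numeric vector.
#' @param rate sampling rate in Hz (>= 200; bare vectors only).
#' @param refine_ms half-width (ms) of the fiducial-refinement window.
#' @return an `rpeak_set`.
#' @export
pan_tompkins <- function(record, rate = NULL, refine_ms = 100) {
  x <- record_samples(record)
  r <- record_rate(record, rate)
  if (r < 200) stop_param("pan_tompkins requires rate >= 200 Hz")
  n <- length(x)

  bp <- zero_phase_filter(signal::butter(2, c(5, 15) / (r / 2), type = "pass"), x, r)
  d <- filter(bp, filter = c(2, 1, 0, -1, -2) / 8, method = "convolution",
              sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  wlen <- ms_to_samples(150, r)
  integ <- as.numeric(filter(sq, rep(1 / wlen, wlen), method = "convolution",
                             sides = 2))
  integ[is.na(integ)] <- 0

  cand <- local_maxima(integ)
  if (length(cand) == 0L) return(new_rpeak_set(integer(0), rate = r))

  # adaptive dual thresholds (Pan-Tompkins running estimates)
  init <- integ[seq_len(min(n, 2L * r))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  thr1 <- function() npki + 0.25 * (spki - npki)
  refractory <- ms_to_samples(250, r)
  qrs <- integer(0)
  rr_avg <- r  # running average RR in samples, init 1 s
  last <- -refractory
  for (i in cand) {
    if (i - last < refractory) {
      if (length(qrs) && integ[i] > integ[qrs[length(qrs)]]) {
        qrs[length(qrs)] <- i; last <- i
      }
      next
    }
    if (integ[i] > thr1()) {
      qrs <- c(qrs, i); last <- i
      spki <- 0.125 * integ[i] + 0.875 * spki
      if (length(qrs) >= 2L) {
        rr_avg <- 0.875 * rr_avg + 0.125 * (qrs[length(qrs)] - qrs[length(qrs) - 1L])
      }
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
      # search-back: accept the best sub-threshold candidate at half thr1
      if (length(qrs) && (i - last) > 1.66 * rr_avg && integ[i] > 0.5 * thr1()) {
        qrs <- c(qrs, i); last <- i
        spki <- 0.25 * integ[i] + 0.75 * spki
      }
    }
  }
  if (length(qrs) == 0L) return(new_rpeak_set(integer(0), rate = r))

  rw <- ms_to_samples(refine_ms, r)
  refined <- vapply(qrs, function(i) {
    lo <- max(1L, i - rw); hi <- min(n, i + rw)
    lo + which.max(abs(x[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  if (length(refined) > 1L) {
    repeat {
      gaps <- diff(refined)
      j <- which(gaps < refractory)
      if (length(j) == 0L) break
      j <- j[1]
      drop <- if (abs(x[refined[j]]) >= abs(x[refined[j + 1L]])) j + 1L else j
      refined <- refined[-drop]
    }
  }
  new_rpeak_set(refined, rate = r)
}

#' Match detected peaks against ground truth
#'
#' Greedy one-to-one matching of detected to truth indices within a time
#' tolerance, yielding sensitivity and positive predictive value.
#'
#' @param truth_idx integer truth R indices.
#' @param detected_idx integer detected R indices (e.g.
#'   `accepted_peaks(peaks)`).
#' @param rate sampling rate in Hz.
#' @param tol_ms match tolerance in ms (default 25).
#' @return list with `tp`, `fp`, `fn`, `sensitivity`, `ppv`.
#' @export
detection_stats <- function(truth_idx, detected_idx, rate, tol_ms = 25) {
  tol <- tol_ms / 1000 * rate
  truth_idx <- sort(truth_idx); detected_idx <- sort(detected_idx)
  used <- logical(length(detected_idx))
  tp <- 0L
  for (t in truth_idx) {
    d <- abs(detected_idx - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  fp <- length(detected_idx) - tp
  fn <- length(truth_idx) - tp
  list(tp = tp, fp = fp, fn = fn,
       sensitivity = if (length(truth_idx)) tp / length(truth_idx) else NA_real_,
       ppv = if (length(detected_idx)) tp / length(detected_idx) else NA_real_)
}
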