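LEAD_VOCAB <- c("V4", "V5", "V6", "other")
MATERIAL_VOCAB <- c("Balingen", "Bonn", "P130+B", "P180+B", "Silitex",
                    "reference", "synthetic")

#' One channel of an ECG recording
#'
#' The basic data object of the pipeline: a vector of samples in mV with its
#' sampling rate and study tags (lead position, subject, electrode material,
#' channel role).
#'
#' @param samples numeric samples in mV (finite).
#' @param rate sampling rate in Hz (> 0), default 500.
#' @param lead lead label, one of `r paste(LEAD_VOCAB, collapse = ", ")`.
#' @param subject subject identifier.
#' @param material electrode material tag from the study vocabulary (or a
#'   synthetic "material" name).
#' @param role `"test"` or `"reference"`.
#' @return an `ecg_record`.
#' @export
ecg_record <- function(samples, rate = 500, lead = "other",
                       subject = NA_character_, material = "synthetic",
                       role = c("test", "reference")) {
  role <- match.arg(role)
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples))) {
    stop_param("samples must be finite numeric values")
  }
  assert_scalar_num(rate, "rate", lower = 1e-9)
  if (!lead %in% LEAD_VOCAB) {
    stop_param("lead must be one of: %s", paste(LEAD_VOCAB, collapse = ", "))
  }
  if (!is.character(material) || length(material) != 1L || !nzchar(material)) {
    stop_param("material must be a non-empty string (study vocabulary: %s; synthetic study materials may use any tag)",
               paste(MATERIAL_VOCAB, collapse = ", "))
  }
  structure(list(samples = as.numeric(samples), rate = rate, lead = lead,
                 subject = as.character(subject), material = material,
                 role = role),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %.1f s @ %g Hz | lead %s | subject %s | %s (%s)\n",
              length(x$samples) / x$rate, x$rate, x$lead, x$subject,
              x$material, x$role))
  invisible(x)
}

#' Convert a labelled synthetic record to an ecg_record
#'
#' @param record a `labeled_record`.
#' @inheritParams ecg_record
#' @return an `ecg_record` (annotations dropped).
#' @export
as_ecg_record <- function(record, lead = "other", subject = NA_character_,
                          material = "synthetic", role = "test") {
  ecg_record(record$signal, record$rate, lead = lead, subject = subject,
             material = material, role = role)
}

#' Write / read a record as CSV
#'
#' The CSV dialect: a header row, a `time_s` column on a uniform grid and
#' one column per channel (default `signal_mV`), values written with 9
#' significant digits so a round trip reproduces the samples bit-exactly at
#' double precision read-back. An optional sidecar annotation CSV holds
#' 1-based R-peak sample indices in a single `r_index` column.
#'
#' @param record an `ecg_record` or `labeled_record`.
#' @param path output CSV path.
#' @param annotation_path optional sidecar path for R indices (written for
#'   `labeled_record`s when given).
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, annotation_path = NULL) {
  x <- record_samples(record)
  rate <- record_rate(record)
  df <- data.frame(time_s = format((seq_along(x) - 1) / rate, digits = 12,
                                   scientific = FALSE, trim = TRUE),
                   signal_mV = format(x, digits = 9, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(annotation_path) && inherits(record, "labeled_record")) {
    write.csv(data.frame(r_index = record$r_idx), annotation_path,
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_record
#' @param format input format; only `"csv"` is implemented. The `"wfdb"` and
#'   `"edf"` identifiers are reserved and error informatively.
#' @param channel channel column to read.
#' @param ... tags passed to [ecg_record()].
#' @return `read_record` returns an `ecg_record`.
#' @export
read_record <- function(path, format = c("csv", "wfdb", "edf"),
                        channel = "signal_mV", ...) {
  format <- match.arg(format)
  if (format != "csv") {
    stop_param("format '%s' is not supported by this build; supply CSV", format)
  }
  if (!file.exists(path)) stop_param("no such file: %s", path)
  df <- read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop_param("CSV must contain a time_s column")
  if (!channel %in% names(df)) stop_param("no channel column '%s' in %s", channel, path)
  t <- df$time_s
  if (length(t) < 2L) stop_param("record too short")
  dt <- diff(t)
  if (max(abs(dt - median(dt))) > 1e-6 * median(dt)) {
    stop_param("non-uniform time grid in %s (jitter above 1 ppm)", path)
  }
  ecg_record(df[[channel]], rate = 1 / median(dt), ...)
}

#' Study configuration
#'
#' Options of the end-to-end evaluation run.
#'
#' @param detector `"pan_tompkins"` or a trained `qrs_segmenter` model; the
#'   detector is run on the reference channel, which anchors the beat
#'   windows of both channels.
#' @param detector_cfg a [detector_config()].
#' @param windows a [segment_windows()].
#' @param use_normalized compute the quality indices on normalized MCPs.
#' @param trim_s seconds discarded at each record edge before detection, to
#'   keep filter transients out of the analysis.
#' @param verify apply correlation verification to detected peaks.
#' @param filter run the Butterworth preprocessing chain.
#' @param min_beats_warn warn when fewer usable beats than this remain.
#' @return a `study_config` list.
#' @export
study_config <- function(detector = "pan_tompkins",
                         detector_cfg = detector_config(),
                         windows = segment_windows(),
                         use_normalized = TRUE, trim_s = 2, verify = TRUE,
                         filter = TRUE, min_beats_warn = 10L) {
  structure(list(detector = detector, detector_cfg = detector_cfg,
                 windows = windows, use_normalized = use_normalized,
                 trim_s = trim_s, verify = verify, filter = filter,
                 min_beats_warn = min_beats_warn),
            class = "study_config")
}

#' Simulate a full paired-electrode study
#'
#' Builds an in-memory study layout: per subject and lead one reference
#' channel is generated, and per material the corresponding test channel is
#' derived from it with that material's electrode distortion. Seeds are
#' derived deterministically from `seed` per (subject, lead, material).
#'
#' @param materials named list of [electrode_distortion()] objects; names
#'   become material tags.
#' @param n_subjects number of subjects.
#' @param leads character vector of lead positions.
#' @param config a [record_config()] template for the reference channels
#'   (its seed field is overridden per record).
#' @param template a [beat_template()].
#' @param seed master seed.
#' @return a tibble with columns `subject`, `material`, `lead` and list
#'   columns `test`, `reference` holding `ecg_record`s.
#' @export
simulate_study <- function(materials, n_subjects = 5, leads = c("V4", "V5", "V6"),
                           config = record_config(), template = beat_template(),
                           seed = 1L) {
  if (is.null(names(materials)) || any(names(materials) == "")) {
    stop_param("`materials` must be a named list of electrode_distortions")
  }
  rows <- list()
  for (s in seq_len(n_subjects)) {
    subj <- sprintf("S%02d", s)
    for (li in seq_along(leads)) {
      cfg <- config
      cfg$seed <- (seed * 7919L + s * 101L + li) %% .Machine$integer.max
      ref <- generate_record(cfg, template)
      ref_rec <- as_ecg_record(ref, lead = leads[li], subject = subj,
                               material = "reference", role = "reference")
      for (mi in seq_along(materials)) {
        test <- apply_electrode(ref, materials[[mi]],
                                seed = cfg$seed + 31L * mi)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = subj, material = names(materials)[mi], lead = leads[li],
          test = list(as_ecg_record(test, lead = leads[li], subject = subj,
                                    material = names(materials)[mi],
                                    role = "test")),
          reference = list(ref_rec))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the end-to-end evaluation
#'
#' For each (subject, material, lead) pair: preprocess both channels, trim
#' the record edges, detect and verify R-peaks on the reference channel,
#' window both channels at the same indices, form the median cardiac
#' periods, score the four segments with R/SNR/PRD, and compute the R-peak
#' amplitude difference on the raw MCPs. Pairs that fail any stage are
#' excluded with a logged reason, never silently dropped.
#'
#' @param layout tibble as produced by [simulate_study()]; columns
#'   `subject`, `material`, `lead` and list columns `test`, `reference`
#'   (each an `ecg_record`), or `test_path`/`ref_path` columns of CSV files.
#' @param config a [study_config()].
#' @return a `study_results` list: `metrics` (tidy tibble: subject,
#'   material, lead, segment, R, SNR_dB, PRD_pct), `amplitudes` (R-peak
#'   amplitude differences in mV), `log` (per-pair beat counters), and
#'   `exclusions`.
#' @export
run_study <- function(layout, config = study_config()) {
  needed <- c("subject", "material", "lead")
  if (!all(needed %in% names(layout))) {
    stop_param("layout must have columns subject, material, lead")
  }
  has_objects <- all(c("test", "reference") %in% names(layout))
  if (!has_objects && !all(c("test_path", "ref_path") %in% names(layout))) {
    stop_param("layout needs test/reference record columns or *_path columns")
  }
  metrics <- list(); amplitudes <- list(); logs <- list(); excl <- list()

  for (i in seq_len(nrow(layout))) {
    row <- layout[i, ]
    res <- tryCatch({
      test <- if (has_objects) row$test[[1]] else read_record(row$test_path)
      ref <- if (has_objects) row$reference[[1]] else read_record(row$ref_path)
      if (test$rate != ref$rate) stop_param("test/reference rate mismatch")
      n <- min(length(test$samples), length(ref$samples))
      xt <- test$samples[seq_len(n)]; xr <- ref$samples[seq_len(n)]
      rate <- ref$rate
      if (config$filter) {
        xt <- preprocess_record(xt, rate)
        xr <- preprocess_record(xr, rate)
      }
      trim_n <- ms_to_samples(config$trim_s * 1000, rate)
      keep <- (trim_n + 1L):(n - trim_n)
      if (length(keep) < rate) stop_param("record too short after edge trimming")
      xt <- xt[keep]; xr <- xr[keep]

      peaks <- if (inherits(config$detector, "qrs_segmenter")) {
        probs <- predict_probabilities(config$detector, xr, rate = rate)
        detect_rpeaks(xr, probs, config$detector_cfg, rate = rate)
      } else if (identical(config$detector, "pan_tompkins")) {
        pan_tompkins(xr, rate = rate)
      } else {
        stop_param("unknown detector")
      }
      n_detected <- sum(peaks$accepted)
      if (config$verify) {
        peaks <- verify_by_correlation(xr, peaks, config$detector_cfg, rate = rate)
      }
      idx <- accepted_peaks(peaks)
      if (length(idx) == 0L) stop_param("no accepted beats")
      per_ref <- extract_periods(xr, rate, idx)
      per_test <- extract_periods(xt, rate, idx)
      mcp_ref <- compute_mcp(per_ref)
      mcp_test <- compute_mcp(per_test)
      scores <- score_pair(mcp_test, mcp_ref, config$windows,
                           config$use_normalized)
      delta <- amplitude_difference(mcp_test, mcp_ref)
      if (nrow(per_ref$beats) < config$min_beats_warn) {
        warning(sprintf("pair %s/%s/%s: only %d usable beats",
                        row$subject, row$material, row$lead,
                        nrow(per_ref$beats)), call. = FALSE)
      }
      list(scores = scores, delta = delta,
           log = tibble::tibble(subject = row$subject, material = row$material,
                                lead = row$lead, beats_detected = n_detected,
                                beats_rejected = n_detected - length(idx),
                                beats_skipped_edge = per_ref$n_skipped,
                                beats_used = nrow(per_ref$beats)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        subject = row$subject, material = row$material, lead = row$lead,
        reason = conditionMessage(res))
      next
    }
    metrics[[length(metrics) + 1L]] <- dplyr::mutate(
      res$scores, subject = row$subject, material = row$material,
      lead = row$lead, .before = 1)
    amplitudes[[length(amplitudes) + 1L]] <- tibble::tibble(
      subject = row$subject, material = row$material, lead = row$lead,
      test_mv = res$delta$test_mv, reference_mv = res$delta$reference_mv,
      delta_mv = res$delta$delta_mv)
    logs[[length(logs) + 1L]] <- res$log
  }
  structure(list(metrics = dplyr::bind_rows(metrics),
                 amplitudes = dplyr::bind_rows(amplitudes),
                 log = dplyr::bind_rows(logs),
                 exclusions = dplyr::bind_rows(excl)),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d metric rows, %d pairs, %d exclusion(s)\n",
              nrow(x$metrics), nrow(x$log), nrow(x$exclusions)))
  invisible(x)
}

#' Pairwise material comparison
#'
#' Shapiro-Wilk gate and pairwise Mann-Whitney tests between materials on
#' pooled per-subject metric values for a chosen segment.
#'
#' @param results a `study_results`.
#' @param value_col metric column (`"R"`, `"SNR_dB"` or `"PRD_pct"`).
#' @param segment segment key, default `"MCP"`.
#' @param alpha significance level.
#' @return tibble of pairwise results with columns `material_a`,
#'   `material_b`, `U`, `p_value`, `reject`, plus per-material normality
#'   p-values as attribute `"shapiro"`.
#' @export
compare_materials <- function(results, value_col = "SNR_dB", segment = "MCP",
                              alpha = 0.05) {
  rows <- dplyr::filter(results$metrics, .data$segment == !!segment)
  mats <- unique(rows$material)
  values <- lapply(mats, function(m) {
    v <- rows[[value_col]][rows$material == m]
    v[is.finite(v)]
  })
  names(values) <- mats
  sw <- vapply(values, function(v) {
    if (length(v) >= 3) shapiro_wilk(v)$p_value else NA_real_
  }, numeric(1))
  out <- list()
  if (length(mats) >= 2L) {
    for (i in seq_len(length(mats) - 1L)) {
      for (j in (i + 1L):length(mats)) {
        mw <- mann_whitney(values[[i]], values[[j]], alpha = alpha)
        out[[length(out) + 1L]] <- tibble::tibble(
          material_a = mats[i], material_b = mats[j], U = mw$statistic,
          p_value = mw$p_value, reject = mw$reject)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "shapiro") <- sw
  res
}

#' Write the report files of a study
#'
#' Emits, under `out_dir`: the tidy metric rows (`metrics.csv`), one median
#' summary table per metric with positions plus a pooled row
#' (`median_R.csv`, `median_SNR_dB.csv`, `median_PRD_pct.csv`), amplitude
#' differences (`amplitude_delta.csv`), box-plot outlier counts per
#' material/segment (`outliers.csv`), pairwise test results (`tests.csv`)
#' and a run manifest with a configuration hash (`manifest.csv`). Output is
#' deterministic: identical results and configuration give byte-identical
#' files.
#'
#' @param results a `study_results`.
#' @param out_dir output directory (created if missing).
#' @param config the [study_config()] used (hashed into the manifest).
#' @return character vector of written paths, invisibly.
#' @export
emit_report <- function(results, out_dir, config = study_config()) {
  if (nrow(results$metrics) == 0L) stop_param("no results to report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(results$metrics, "metrics.csv")
  for (metric in c("R", "SNR_dB", "PRD_pct")) {
    med <- median_summary(results$metrics, metric)
    wide <- tidyr::pivot_wider(med[, c("material", "lead", "segment", "median")],
                               names_from = "material", values_from = "median")
    wr(dplyr::arrange(wide, .data$lead, .data$segment),
       sprintf("median_%s.csv", metric))
  }
  wr(results$amplitudes, "amplitude_delta.csv")

  out_rows <- results$metrics |>
    dplyr::group_by(.data$material, .data$segment) |>
    dplyr::group_modify(function(d, ...) {
      counts <- vapply(c("R", "SNR_dB", "PRD_pct"), function(m) {
        v <- d[[m]][is.finite(d[[m]])]
        if (length(v) >= 4) box_stats(v)$n_outliers else NA_integer_
      }, integer(1))
      tibble::tibble(metric = c("R", "SNR_dB", "PRD_pct"),
                     n_outliers = counts)
    }) |>
    dplyr::ungroup()
  wr(out_rows, "outliers.csv")

  tests <- compare_materials(results)
  if (nrow(tests)) wr(tests, "tests.csv")

  wr(tibble::tibble(key = c("config_hash", "n_pairs", "n_exclusions"),
                    value = c(config_hash(config), nrow(results$log),
                              nrow(results$exclusions))),
     "manifest.csv")
  invisible(paths)
}

#' Hash of a configuration object
#'
#' MD5 of the deparsed configuration; changes iff the configuration (or an
#' embedded model's weights) changes.
#'
#' @param config any R object (typically a [study_config()]).
#' @return 32-character hash string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  if (inherits(config$detector, "qrs_segmenter")) {
    config$detector <- list(wts = round(config$detector$net$wts, 12),
                            n_scales = config$detector$n_scales,
                            seed = config$detector$seed)
  }
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}
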