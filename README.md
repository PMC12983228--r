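# ecgqc — signal-quality scoring of alternative ECG electrodes

`ecgqc` quantifies how faithfully an alternative ECG electrode (for
example a dry textile electrode sewn into a garment) reproduces the signal
of a conventional Ag/AgCl reference electrode recorded simultaneously at
the same chest position. It is aimed at groups developing wearable ECG
hardware who need a reproducible, statistically grounded answer to "is
this electrode good enough?".

## Method

A recording pair is reduced to two **median cardiac periods (MCPs)**:
R-peaks are detected on the reference channel, both channels are windowed
from R−250 ms to R+450 ms at the same indices, and the sample-wise median
across beats forms a 700 ms beat template per channel (robust to transient
artifacts in up to half the beats). The test MCP *y* is scored against the
reference MCP *x* — whole and per P/QRS/T segment — with three
complementary indices:

    R   = Σ(xᵢ−x̄)(yᵢ−ȳ) / √(Σ(xᵢ−x̄)² Σ(yᵢ−ȳ)²)        (shape)
    SNR = 10·log₁₀( Σxᵢ² / Σ(xᵢ−yᵢ)² )  dB               (error power)
    PRD = 100·√( Σ(yᵢ−xᵢ)² / Σxᵢ² )  %                    (relative error)

plus the absolute R-peak amplitude difference in mV on the raw MCPs.
Detection uses continuous-wavelet-transform scalograms and a trainable
per-sample Q/R/S classifier with a morphological constraint (an R must sit
between predicted Q and S waves) and correlation-based beat verification;
a classical Pan–Tompkins detector is included as a comparator. Group
comparison across electrode materials uses per-material medians by lead
position, Tukey box-plot outlier counts, a Shapiro–Wilk normality gate and
Mann–Whitney rank-sum tests at α = 0.05 (exact by enumeration at small n).

A fully seeded synthetic paired-electrode generator (Gaussian-sum beats,
baseline drift, 50 Hz hum, broadband noise, per-wave amplitude distortion,
motion bursts) provides ground truth for every stage, so the whole
pipeline is testable without any recorded data.

## Worked example

```r
library(ecgqc)

# a reference channel and two simulated test electrodes of graded quality
mats <- list(
  good = electrode_distortion(extra_noise_sd_mv = 0.01),
  poor = electrode_distortion(extra_noise_sd_mv = 0.1, extra_drift_mv = 0.1,
                              wave_scale = c(P = 1, Q = 1, R = 0.9, S = 1.2, T = 1)))
layout <- simulate_study(mats, n_subjects = 4, leads = c("V4", "V5"),
                         config = record_config(duration_s = 30), seed = 1)
res <- run_study(layout, study_config())

med <- median_summary(dplyr::filter(res$metrics, segment == "MCP"), "SNR_dB")
med[med$lead == "pooled", c("material", "median")]
#> # A tibble: 2 x 2
#>   material median
#>   <chr>     <dbl>
#> 1 good       42.6
#> 2 poor       15.1

head(res$amplitudes[res$amplitudes$material == "poor", "delta_mv"][[1]], 2)
#> [1] 0.08048692 0.09694449
```

The pooled median SNR separates the two electrodes by more than 25 dB, and
the `poor` electrode's 10 % R-wave scaling shows up directly as a
≈0.08–0.10 mV R-peak amplitude difference on a ~1 mV beat. `emit_report(res, "out/")`
writes the median tables (one per metric, positions plus a pooled row),
outlier counts, pairwise Mann–Whitney results and a run manifest as CSV.

## Command-line use

A thin CLI over the same functions lives at `inst/cli/ecgqc` (simulate a
labelled record to CSV, detect peaks on a CSV record, evaluate a study
layout); see `inst/cli/ecgqc --help`. The R functions above remain the
primary interface.
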