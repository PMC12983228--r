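---
title: "Scoring alternative ECG electrodes against a reference channel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring alternative ECG electrodes against a reference channel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgqc)
```

## The problem

Dry textile electrodes are attractive for wearable ECG — no gel, no skin
irritation, washable garments — but their contact impedance is higher and
less stable than that of adhesive Ag/AgCl electrodes, so they pick up more
baseline wander, more motion artifact, and sometimes distort wave
amplitudes. The question this package answers is quantitative: *given a
test electrode recorded simultaneously with a reference Ag/AgCl electrode
at the same chest position, how faithfully does the test channel reproduce
the reference?*

The unit of comparison is not the raw signal (which mixes beat-to-beat
physiological variation with electrode behaviour) but the **median cardiac
period (MCP)**: all beats of a recording are windowed from 250 ms before to
450 ms after the R-peak, and the sample-wise median across beats forms a
700 ms beat template per channel. Comparing the two channels' MCPs — as a
whole and within P, QRS and T sub-segments — isolates what the electrode
does to the waveform.

## Pipeline overview

1. **Preprocessing** — two zero-phase IIR Butterworth filters at 500 Hz:
   band-pass 0.5–100 Hz, then band-stop 49–51 Hz against mains hum, both of
   order 2.
2. **R-peak detection** on the reference channel: continuous wavelet
   transform (analytic Morlet) scalograms feed a trainable per-sample
   classifier producing probability series for the classes background, Q,
   R and S; R candidates are probability maxima above a threshold that are
   flanked by Q and S maxima; positions are refined to the signal extremum;
   detected beats are verified by correlation against their median excerpt.
3. **Beat analysis** — both channels are windowed at the *same* reference
   R indices, MCPs formed and min–max normalized.
4. **Quality indices** per segment (full MCP, P, QRS, T), with
   \(x\) the reference slice and \(y\) the test slice:
   \[
   R = \frac{\sum_i (x_i-\bar x)(y_i-\bar y)}
            {\sqrt{\sum_i (x_i-\bar x)^2\sum_i (y_i-\bar y)^2}},\qquad
   \mathrm{SNR} = 10\log_{10}\frac{\sum_i x_i^2}{\sum_i (x_i-y_i)^2}\ \mathrm{dB},
   \]
   \[
   \mathrm{PRD} = 100\sqrt{\frac{\sum_i (y_i-x_i)^2}{\sum_i x_i^2}}\ \%.
   \]
   The three are complementary: R sees only shape (it is affine-invariant
   in either argument), while SNR and PRD see amplitude error; PRD and SNR
   are algebraic duals, \( \mathrm{PRD} = 100\cdot 10^{-\mathrm{SNR}/20} \).
   The **R-peak amplitude difference** \(|y_{R} - x_{R}|\) read off the
   *raw* (unnormalized) MCPs complements them with an absolute amplitude
   fidelity number in mV.
5. **Group statistics** — per-material medians by lead position plus a
   pooled row, box-plot summaries with Tukey 1.5·IQR outliers, a
   Shapiro–Wilk normality gate, and Mann–Whitney rank-sum comparisons at
   \(\alpha = 0.05\).

## The synthetic paired-electrode generator

Every stage is testable without recorded data because the package ships a
fully seeded generator:

- **Beat model**: a sum of five Gaussians (P, Q, R, S, T), each with a
  signed amplitude (mV), a centre offset from R (ms) and a width (ms).
  This parametric form gives exact ground truth — R positions, a
  per-sample Q/R/S label mask (±10 ms around each wave centre), and the
  true R amplitude used by amplitude-difference oracles.
- **Record model**: beats placed at RR intervals around a configured heart
  rate (default 60 bpm) with truncated-normal jitter (±3 sd, so RR stays
  physiological), plus baseline drift (default 0.15 mV at 0.3 Hz), 50 Hz
  hum (default 0.05 mV) and white noise (default 0.02 mV). The drift and
  noise amplitudes are free parameters of the generator — chosen here as
  typical resting-ECG artifact levels in mV terms — since only their
  presence, not their magnitude, is prescribed by the study design the
  generator emulates.
- **Electrode model**: the test channel re-renders the clean beat
  component with per-wave amplitude scale factors (e.g. a reduced R or
  deepened S, the classic dry-electrode signature), keeps the shared
  drift/hum/noise (both electrodes see the same heart and the same mains
  field), and adds electrode-specific extra drift, extra white noise,
  Poisson-placed 500 ms random-walk motion bursts, and an optional channel
  lag.
- `requested_snr_pair()` builds calibrated pairs: the injected noise vector
  is rescaled in closed form to energy \(\sum x^2 \cdot 10^{-\mathrm{SNR}/10}\),
  so the realized SNR equals the request exactly.

What the generator does **not** emulate: respiration coupling, arrhythmia,
electrode-skin impedance drift over minutes, or 12-lead spatial structure.
Tests passing on synthetic data therefore demonstrate the pipeline's
*mechanics* (windowing, medians, metrics, detection logic), not clinical
performance on pathological ECG.

## The R-peak detector

The paper-shaped detector has two unusual properties worth explaining:

- **Morphological context**: a candidate R (a local maximum of the R
  probability series above \(\theta_R = 0.5\)) is only kept if a Q-class
  probability maximum precedes it and an S-class maximum follows it within
  100 ms. This is what lets it survive the deep-S/low-R morphology that
  defeats amplitude-threshold detectors such as Pan–Tompkins: the decision
  uses the whole QRS shape, not the tallest deflection.
- **Correlation verification**: every detected beat's ±150 ms excerpt is
  correlated against the sample-wise median of all excerpts; beats below
  \(\rho_{\min} = 0.8\) are rejected in one pass, after which the template
  and the reported correlations are recomputed once from the survivors.
  (No second rejection round: a single pass keeps the operation idempotent
  on clean records.)

The per-sample classifier is a single-hidden-layer softmax network (16
hidden units) over each sample's scalogram column — 32 Morlet scales
log-spaced over 1–45 Hz, z-normalized per scale within 2048-sample analysis
windows (50 % overlap, probabilities averaged where windows overlap) —
concatenated with the window-normalized signal value at nine lags from
−40 ms to +40 ms. The lag features restore the polarity and the
Q-before-R-before-S timing that the magnitude scalogram discards; without
them Q and S are nearly indistinguishable and held-out sensitivity drops by
double digits. Training uses inverse-frequency class weights (background
dominates the label mask roughly 30:1 even after subsampling background
samples at 2:1 against labelled ones) and weight decay (`1e-4`) as the
regularizer; all initialization and subsampling flows from one seed, so
training is bit-reproducible single-threaded.

Training data are synthetic only, drawn from `training_records()`: twenty
30-second records spanning R amplitudes 0.5–1.5 mV, heart rates 50–90 bpm,
variable artifact levels, and — in every fourth record — an S wave deeper
than the R wave. The model is deliberately tiny (≈ 1500 weights,
minutes to train on one CPU); the point is a faithful, testable
implementation of the detection *architecture*, not a clinically trained
model.

The classical Pan–Tompkins chain (5–15 Hz band-pass, derivative, squaring,
150 ms integration, adaptive dual thresholds with search-back) is included
as a comparator. Its fiducial refinement picks the largest absolute signal
excursion near the integrated-energy peak — which is exactly why it
mislocates beats whose S wave is deeper than the R wave is tall, while the
segmentation detector does not. On clean records the two agree on
essentially every beat, which is the mutual sanity check the tests encode.

## Numerical and design choices

- **Zero-phase filtering** (forward–backward with odd-reflection padding of
  3 s): the two channels must keep zero relative delay or the sample-wise
  MCP comparison would punish pure phase shifts. This doubles the effective
  filter order; since it is applied identically to both channels, pairwise
  metrics are unaffected.
- **Windows are half-open and ms-denominated**: the beat window is
  \[R-250\,\mathrm{ms}, R+450\,\mathrm{ms})\) at any rate — 350 samples with
  R at local index 125 (0-based) at 500 Hz. Segment defaults are
  P \([-250,-60)\), QRS \([-60,+60)\), T \([+120,+450)\) ms; the boundaries
  are configurable because no standard prescribes them, and they are a
  deliberate implementation choice of this package.
- **Normalization** is min–max to \([0,1]\) of the raw median; metrics run
  on normalized MCPs by default (a `use_normalized = FALSE` switch allows
  raw-mV sensitivity analysis), while the amplitude difference always uses
  raw MCPs so mV values stay meaningful.
- **Reference channel anchors the windows** of both channels: detection
  runs once, on the cleaner channel, and identical indices slice both
  signals, so the metrics compare waveforms, not detector jitter.
- **Identical channels** yield zero error power; SNR then returns `Inf`,
  which summaries treat as a sentinel — excluded from medians and counted
  separately — rather than propagating infinities into tables.
- **Mann–Whitney**: U from midranks; exact p by full enumeration of group
  labelings for pooled sizes ≤ 16 (two-sided p as the probability of a
  \(|U-\mu|\) at least as extreme); beyond that a continuity-corrected
  normal tail with an Edgeworth kurtosis term
  (\(\gamma_2 = -\tfrac{6}{5}(n_a^2+n_b^2+n_an_b+n_a+n_b)/(n_an_b(n+1))\)),
  which keeps the approximation within about \(10^{-3}\) of exact at
  \(n_a=n_b=8\) instead of the \(\sim 10^{-2}\) of the plain normal. No
  multiple-testing correction is applied by default (single per-comparison
  \(\alpha\)); the comparison table reports raw p-values.
- **Shapiro–Wilk** delegates to the standard Royston implementation in
  `stats`; the suite verifies its calibration (type-I error within
  \([0.03, 0.07]\) at \(\alpha=0.05\), \(n=50\), 2000 replicates) rather
  than its internals.
- **Degenerate inputs** error loudly: constant vectors (undefined
  correlation), all-zero references (undefined SNR/PRD), constant medians
  (degenerate normalization), too-short signals for the filter transient.
  In `run_study()` such failures exclude the pair *with a logged reason*;
  the pair count always equals processed + excluded.

## Problem sizes used by the tests

The shipped test-suite and acceptance run use deliberately desk-scale
sizes: 30-second records, a 20-record training corpus, 10 held-out records,
a five-"material" graded study of 20 subjects × 3 leads, and 1000-vector
random suites for the metric oracles. These sizes are the package's own
test design: large enough that every monotonicity and calibration property
is resolvable, small enough that the whole suite runs on one CPU in
minutes.

## Known limitations

- The detector is trained on synthetic morphologies; nothing here claims
  clinical-grade performance on pathological or paediatric ECG.
- The CSV dialect is the only record format implemented; WFDB/EDF
  identifiers are reserved but unimplemented.
- Segment boundaries are fixed per run, not adapted to heart rate; at very
  high rates the T window of a default configuration can overlap the next
  beat.
- Correlation verification assumes a dominant uniform beat morphology; in
  bigeminy-like alternating morphologies it would reject every second
  beat.
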