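---
title: "Processing task-based fNIRS recordings with optoflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing task-based fNIRS recordings with optoflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoflow)
```

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
through the attenuation of near-infrared light between scalp optodes at two
wavelengths. The measured intensities mix the quantity of interest —
task-evoked oxy- (HbO) and deoxyhemoglobin (HbR) concentration changes in
cortex — with cardiac pulsation (~1 Hz), respiration (~0.3 Hz), slow drift,
motion artifacts, and, most troublesome, low-frequency (LF, 0.01–0.15 Hz)
systemic oscillations that overlap the task frequency band and travel through
the whole head with spatially varying delays. Every published pipeline makes a
series of choices — which channels to exclude, how to correct motion, which
filter to use, how to remove the LF global signal, how to model activation —
and these choices materially change single-subject conclusions.

`optoflow` implements each of these stages as an explicit, tested operation,
plus a synthetic-recording generator with known ground truth so that every
stage's behavior can be measured rather than assumed.

## The processing model

The stage order is: channel exclusion (on raw intensity / optical density) →
intensity to optical density → wavelet motion correction → zero-phase
band-pass → LF de-noising → (conversion to concentration) → prewhitened
robust GLM. PCA and the delay-corrected global average operate on filtered
optical density with conversion afterwards; short-separation regression
operates on concentrations. This asymmetry mirrors how the methods are
conventionally deployed and is preserved deliberately.

### Optics: the modified Beer-Lambert law

Relative optical density is `OD(t) = -log(I(t)/mean(I))` (natural log). Per
channel, the two-wavelength system

$$\frac{\Delta OD(\lambda)}{d \cdot DPF(\lambda)} =
  \epsilon_{HbO}(\lambda)\,\Delta HbO + \epsilon_{HbR}(\lambda)\,\Delta HbR$$

is solved for the two chromophores, with `d` the source–detector distance in
mm and the differential path length factor from the published
age-and-wavelength general equation
(`dpf_age()`; coefficients 223.3, 0.05624, 0.8493, −5.723e-7, 0.001245,
−0.9025). The equation was validated for frontotemporal adult/child heads;
occipital accuracy is not established. Extinction coefficients are the Prahl
compilation, converted to natural-log units of mm⁻¹ µM⁻¹ and shipped as a
versioned CSV (`inst/extdata/extinction_coefficients.csv`), so distances in
mm yield concentrations in µM.

### Channel exclusion

Two automated rules are provided. The coefficient of variation
(`cv_exclusion()`, threshold 7.5%, strict inequality, sample SD, channel
statistic = max over the two wavelengths — the conservative aggregation) flags
high-noise channels on raw intensity. The windowed coupling rule
(`phoebe_exclusion()`) splits each channel into non-overlapping 3 s windows
(trailing partial window dropped) and requires, per window, a scalp coupling
index ≥ 0.7 *and* a cardiac cross-spectral power ≥ 0.1; a channel survives
when ≥ 80% of its windows pass. The 80% acceptance is applied over windows
(the alternative — over samples — is equivalent here because windows have
equal length).

Two numerical choices matter at this sampling rate (3.9062 Hz, 11 samples per
window): the SCI band-pass uses an order-1 zero-phase Butterworth, because
higher orders narrow the effective band so far that independent noise exceeds
|r| = 0.7 in well over 5% of windows; and the cardiac power is computed from
the unbiased, energy-normalized cross-correlation of the *raw* windows with
the band selection applied in the spectral domain (Hamming window, zero-padded
FFT, peak squared amplitude within 0.8–1.95 Hz). Band-passing 11-sample
windows before cross-correlating concentrates even independent noise into the
band and destroys the 0.1 threshold's meaning; the spectral-domain restriction
preserves it (Monte-Carlo: ~99% of independent-noise windows below 0.1, all
coupled-cardiac windows above it).

### Wavelet motion correction

Both correctors use a periodized orthogonal Daubechies (db2) filter bank
implemented in the package, with series symmetric-extended to a power of two.
Because the decimated transform is shift-variant, both correctors average over
8 circular shifts (cycle spinning); otherwise an artifact's coefficients can
straddle the threshold purely depending on its alignment with the
downsampling grid.

* **MC#1** (`wavelet_motion_correct()`): within each detail level,
  coefficients outside `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` are zeroed. The
  quartiles stay robust under sparse contamination, so isolated spikes are
  removed with little signal distortion. Note its limits: a 10-SD spike's
  mid-level coefficients can hide inside a fence widened by genuine signal
  content, so per-spike amplitude reduction is ~90–95% on average, not total.
* **MC#2** (`kurtosis_wavelet_motion_correct()`): while the moment kurtosis
  of the detail-coefficient distribution exceeds 3.3, the largest-magnitude
  coefficient is zeroed (zeroed entries stay in the distribution). The
  statistic is pooled across levels by default: pooled multiscale
  coefficients form a scale mixture and are intrinsically leptokurtic, which
  makes this rule shed far more coefficients than MC#1 — reproducing the
  systematic overcompensation this variant is known for. A per-level scope is
  available (`scope = "per_level"`) and is much gentler; with it the ordering
  between the two correctors is *not* stable, which is why pooled is the
  default.

### Band-pass filtering

Three zero-phase filters extract 0.01–0.2 Hz, which brackets the block
design's fundamental `1/(10 s + 15 s) = 0.04 Hz` and its first harmonic
0.08 Hz: a sequential third-order Butterworth (low-pass then high-pass, each
forward–backward), a direct third-order band-pass, and a trapezoidal FFT
filter (unity in [0.01, 0.2] Hz, linear transitions to 0.009 and 0.22 Hz —
our reading of the "−10% / +10%" edge convention; the inverted reading is
available via `edge_side = "inner"`).

All filters apply mirror-reflection padding of `1/lo` seconds. Two numerical
points discovered while validating: (1) point-symmetric (odd) padding shifts
the pad's DC level to `2·x[end]`, which the narrow high-pass stage turns into
a transient long enough to reach the record middle — hence mirror padding;
(2) the FFT filter's padding trades the mathematically hard stop band of the
circular transform (available via `pad = FALSE`) for an order-of-magnitude
reduction in wrap-around edge transients, which otherwise dominate
filter-agreement measurements at the 977-sample record length.

### LF de-noising

* **SSD** (`ssd_denoise()`): each long channel is cleaned by regressing out
  its assigned short (20 mm) channel with a cold-start LMS adaptive filter
  (`mu = 1e-4`, `M = 1`), independently per hemoglobin species — so HbR is
  altered even when only HbO shares variance with the reference. The default
  assignment splits long channels into index halves ("hemispheres"), each
  served by the nearest short channel.
* **PCA** (`pca_denoise()`): the first spatial principal component of the
  filtered OD matrix (long channels, per wavelength) is regressed out of
  every channel. On synchronous global structure PC1 tracks the channel mean;
  on *lagged* global structure the global signal is no longer rank-1 and PCA
  necessarily leaves residual global variance — the motivation for the next
  method.
* **GloAvg** (`lagged_global_average()`): per target channel, every other
  long channel is lag-aligned at its cross-correlation optimum (±5 s
  window); channels with `r > 0.37` are averaged into a per-target global
  signal and regressed out with the same LMS filter. The 0.37 default is the
  conventional empirical-null threshold;
  `correlation_threshold_simulation()` recomputes it for any record length
  and band. Lag convention: positive lag means the partner lags the target;
  shifted-out samples are dropped from the average at the edges.

The LMS step size is specified for a reference internally normalized to
SD 10, making convergence scale-free (time constant ≈ 50 samples at the
default `mu`); a warm-up pass over the series precedes the reported pass so
the cold-start transient does not leak reference variance into the residual.
With `mu = 0` the filter does nothing, by construction.

### Activation statistics

Block metrics use the rest window [−4, 0) s and the task window [5, 15) s
around each onset (5 s hemodynamic delay plus the 10 s task); Cohen's d is
`(mean(dur) − mean(pre))/sd(pre)` and CNR
`|mean(dur) − mean(pre)|/sqrt(var(dur) + var(pre))` over per-block window
means. ROI summaries take the signed maximum for HbO effect sizes, the most
negative value for HbR, and the absolute maximum for CNR.

The GLM design holds an intercept, the block boxcar convolved with the
canonical double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6 — all
configurable, since toolboxes disagree on the peak latency), and optionally
its first and second temporal derivatives, orthogonalized against the
preceding columns so the main-term estimate keeps its interpretation. Errors
are prewhitened with an AR(p) model fitted to OLS residuals — order by BIC up
to `ceiling(4·fs)`, Burg estimates, AR(1) fallback if the fit is
non-stationary — because band-passed hemodynamic series are strongly
autocorrelated and unwhitened t statistics are badly inflated (type-I ~0.5 at
nominal 0.05 on AR(1) noise with φ = 0.8, vs ~0.05–0.08 whitened). The fit is
iteratively reweighted least squares with Tukey's bisquare (c = 4.685);
inference uses the main column's t only. q values are Benjamini–Hochberg
(step-up) across the included long channels, per species — the per-species
family keeps the two chromophores' decisions independent, which the combined
criterion then intersects: a channel is *combined-active* only when HbO rises
significantly **and** HbR falls significantly (q < 0.05 with the canonical
signs). The significance level on q is 0.05, config-exposed.

## The synthetic-recording generator

`simulate_recording()` composes, in concentration space (µM): an HRF-shaped
neural response confined to the ROI channels (HbO amplitude +1 µM and HbR
−1/3 µM with a 1 s extra delay, both defined as the noiseless block-averaged
task-window contrast); a lagged global LF component (0.1 Hz sinusoid plus
band-limited 0.01–0.15 Hz noise, per-channel lags uniform in ±5 s,
per-channel gain 0.8–1.2); cardiac (1 Hz) and respiratory (0.3 Hz)
oscillations; and a linear drift. Systemic components enter HbR scaled by
0.35 with the same sign as HbO (systemic physiology moves both species
together; it is the neural response that moves them apart). The composite is
pushed through the forward Beer-Lambert model into dual-wavelength intensity
around I0 = 1, with white sensor noise (SD 5e-4). "Bad" channels receive no
cardiac component and 10× noise, emulating decoupled optodes. Acquisition
defaults emulate the target study: fs = 3.9062 Hz, 10 blocks of 10 s on /
15 s off, 20 long channels at 30 mm, 2 short at 20 mm, ROI channels 4, 5,
10, 12.

The global LF amplitude default (4.75 µM) was calibrated once so that the
ROI-maximum block Cohen's d without LF de-noising is ≈ 0.8 across seeds
(matching the emulated study's reported effect size, which carries a large
between-subject spread); it is the dominant noise source by design, because
the phenomenon under study is LF contamination of the task band.

What the generator does *not* emulate: 1/f-distributed and heavy-tailed
sensor noise, serially correlated physiological amplitude modulation,
spatially structured (non-global) systemic topographies, partial-volume
differences between scalp and cortex beyond the short/long distinction, and
realistic optode-position geometry. Passing recovery tests on these
simulations therefore demonstrates internal consistency of the pipeline under
the stated noise model, not performance on any particular instrument's data.

## Problem sizes and numerical choices

Tests and the acceptance script use records of 977–1035 samples (the ~250 s
trimmed task segment at 3.9062 Hz), cohorts of 16 simulated subjects for
recovery rates, 500 replicates for type-I calibration, and 8–10 constructed
fixtures for motion-correction and de-noising measurements — sizes chosen so
every claim is recomputed from scratch in minutes on a laptop. Band variance
is measured by periodogram integration (not by re-filtering), because sharp
filters ring at record edges and contaminate short-record variance ratios.
Degenerate inputs (zero-variance windows or references, empty ROIs,
rank-deficient designs, onsets beyond the record) raise informative errors or
flags rather than propagating NaNs; exclusions are carried through as `NA`
rows, never silently dropped.

## Known limitations

* SNIRF I/O covers continuous-wave, two-wavelength recordings with block
  stimuli — the subset this pipeline analyzes — not the full container
  specification.
* The IQR wavelet corrector's spike suppression is ~90–95% per spike on
  average, limited by mid-level coefficients hiding inside signal-widened
  fences; it is not a guarantee per artifact.
* The kurtosis corrector's pooled scope reproduces the known
  overcompensation; treat it as a cautionary baseline, not a recommendation.
* GloAvg needs ≥ 3 mutually correlated long channels and degrades when true
  inter-channel delays exceed the ±5 s search window (partners are then
  rejected, or accepted at a misaligned optimum).
* The GLM models a single known block design; event-related designs and HRF
  estimation are out of scope.

## A short example

```{r example, eval = FALSE}
sim <- simulate_recording(sim_config(), seed = 1)
res <- process_recording(sim$recording,
                         exclude_method = "phoebe",
                         mc_method = "iqr_wavelet",
                         filter_method = "bw_seq",
                         denoise_method = "gloavg")
subset(res$decisions, combined_active)

# factorial comparison of the four de-noising strategies
cfg <- pipeline_config(denoise_method = c("none", "ssd", "pca", "gloavg"),
                       n_subjects = 4, base_seed = 1)
report <- compare_methods(run_pipeline(cfg))
report$detection
```
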