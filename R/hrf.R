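# Canonical double-gamma hemodynamic response function.

#' Canonical HRF kernel
#'
#' Double-gamma impulse response: a gamma peaking at `peak_s` minus a
#' `ratio`-scaled gamma undershoot peaking at `undershoot_s`, normalized to
#' unit peak. Both gammas use unit rate (per second), so the mode of each
#' term falls exactly at its nominal latency. The defaults (peak 6 s,
#' undershoot 16 s, ratio 1/6) follow the convention common in fMRI/fNIRS
#' model-based analysis; all three are configurable because peak latency
#' varies across subjects and toolboxes.
#'
#' @param fs sampling rate in Hz (> 0)
#' @param duration_s kernel support in seconds (>= 30)
#' @param peak_s response peak latency (s), must precede `undershoot_s`
#' @param undershoot_s undershoot latency (s)
#' @param ratio undershoot amplitude relative to the peak (0 disables it)
#' @return numeric kernel sampled at `fs`, peak value 1
#' @export
canonical_hrf <- function(fs, duration_s = 40, peak_s = 6, undershoot_s = 16,
                          ratio = 1 / 6) {
  if (fs <= 0) stop("canonical_hrf: fs must be positive")
  if (peak_s >= undershoot_s) {
    stop("canonical_hrf: peak_s must precede undershoot_s")
  }
  if (duration_s < 30) stop("canonical_hrf: duration_s must be >= 30 s")
  t <- seq(0, duration_s, by = 1 / fs)
  # unit-rate gammas with mode at the nominal latency: shape = latency + 1
  g1 <- stats::dgamma(t, shape = peak_s + 1, rate = 1)
  g2 <- stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h <- g1 / max(g1) - ratio * g2 / max(g2)
  h / max(h)
}

#' Task regressor: block boxcar convolved with the canonical HRF
#'
#' @param stimulus a [stimulus_design()]
#' @param fs sampling rate (Hz)
#' @param n_samples length of the output series
#' @param hrf HRF kernel; defaults to [canonical_hrf()] at `fs`
#' @param onset_shift_s extra delay (s) applied to every block onset, e.g.
#'   to model the slower deoxyhemoglobin response
#' @return numeric vector of length `n_samples` (unit plateau before HRF
#'   scaling)
#' @export
task_regressor <- function(stimulus, fs, n_samples,
                           hrf = canonical_hrf(fs), onset_shift_s = 0) {
  box <- numeric(n_samples)
  for (on in stimulus$onsets + onset_shift_s) {
    i0 <- time_to_index(on, fs)
    i1 <- min(time_to_index(on + stimulus$task_duration, fs) - 1L, n_samples)
    if (i0 <= n_samples && i1 >= max(i0, 1L)) {
      box[max(i0, 1L):i1] <- 1
    }
  }
  conv_full <- stats::convolve(box, rev(hrf), type = "open")
  resp <- conv_full[seq_len(n_samples)]
  # scale so a sustained block reaches a unit plateau
  resp / sum(hrf)
}
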