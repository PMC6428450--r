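# Synthetic dual-wavelength recordings with known ground truth.
#
# Composition (concentration space, uM):
#   hb = neural (ROI only) + lagged global LF + cardiac + respiration + drift
# forward modified Beer-Lambert -> delta-OD, intensity = I0 * exp(-OD) plus
# white sensor noise. Bad channels carry no cardiac component and 10x noise,
# emulating decoupled optodes.

#' Default probe layout for simulations
#'
#' `n_long` long channels at 30 mm plus `n_short` short channels at 20 mm,
#' with a 4-channel motor-cortex-like ROI among the long channels
#' (defaults to indices 4, 5, 10, 12 where available).
#'
#' @param n_long number of long (cortical) channels, >= 1
#' @param n_short number of short (scalp-reference) channels
#' @param roi ROI channel indices; defaults to `c(4, 5, 10, 12)` clipped to
#'   the available long channels
#' @return a [probe_layout()]
#' @export
default_layout <- function(n_long = 20, n_short = 2, roi = NULL) {
  if (n_long < 1) stop("default_layout: n_long must be >= 1")
  if (n_short > n_long) {
    stop("default_layout: more short than long channels is not supported")
  }
  n <- n_long + n_short
  channels <- data.frame(
    source_id = seq_len(n),
    detector_id = seq_len(n),
    distance_mm = c(rep(30, n_long), rep(20, n_short)),
    is_short = c(rep(FALSE, n_long), rep(TRUE, n_short))
  )
  if (is.null(roi)) roi <- intersect(c(4L, 5L, 10L, 12L), seq_len(n_long))
  if (length(roi) == 0) roi <- 1L
  probe_layout(channels, wavelengths = c(760, 850), roi_channels = roi)
}

#' Motion artifact event
#'
#' @param time_s event time in seconds
#' @param kind `"spike"` (Gaussian bump) or `"baseline_shift"` (step)
#' @param amplitude event size in multiples of the channel's OD standard
#'   deviation (non-zero)
#' @param width_s spike full width at half maximum in seconds (ignored for
#'   baseline shifts)
#' @return a list of class `artifact_event`
#' @export
artifact_event <- function(time_s, kind = c("spike", "baseline_shift"),
                           amplitude = 10, width_s = 0.5) {
  kind <- match.arg(kind)
  if (amplitude == 0) stop("artifact_event: amplitude must be non-zero")
  structure(list(time_s = time_s, kind = kind, amplitude = amplitude,
                 width_s = width_s), class = "artifact_event")
}

#' Simulation configuration
#'
#' Defaults reproduce the emulated acquisition: 3.9062 Hz sampling, a
#' 10 s-on / 15 s-off block design repeated 10 times, 30 mm long and 20 mm
#' short channels, cardiac (~1 Hz) and respiratory (~0.3 Hz) oscillations,
#' a lagged global low-frequency (0.01-0.15 Hz) systemic component, slow
#' drift, optional motion events and bad channels. Activation is an HbO
#' increase with a smaller, delayed HbR decrease confined to ROI channels.
#' Component amplitudes are calibrated so that the block-design Cohen's d of
#' the ROI response without LF de-noising is approximately 0.8 (matching the
#' emulated study; the spread across seeds is large, as it is across real
#' subjects).
#'
#' @param n_long,n_short layout sizes (see [default_layout()])
#' @param fs sampling rate, Hz
#' @param design a [stimulus_design()]; default 10 blocks of 10 s on / 15 s
#'   off starting at 15 s
#' @param subject_age years
#' @param activation_hbo_amp ROI HbO block amplitude, uM (> 0); defined as
#'   the noiseless block-averaged task-window contrast
#' @param activation_hbr_amp ROI HbR amplitude, uM (< 0)
#' @param hbr_delay_s extra HbR response latency, s
#' @param global_lf_band global systemic band, Hz
#' @param global_lag_range_s channel lags of the global component drawn
#'   uniformly in `[-x, x]`
#' @param global_amp global LF amplitude (HbO, uM); HbR scaled by
#'   `hbr_physio_scale`
#' @param cardiac_freq,resp_freq physiological frequencies, Hz
#' @param cardiac_amp,resp_amp,drift_amp component amplitudes (HbO, uM)
#' @param hbr_physio_scale HbR amplitude of systemic components relative to
#'   HbO (sign-flipped for none; systemic physiology moves both species in
#'   the same direction)
#' @param noise_sd white sensor-noise SD on intensity (I0 = 1)
#' @param motion_events list of [artifact_event()]s
#' @param bad_channels integer indices of channels simulated as decoupled
#' @param rest_before_s lead-in rest before the first block, s
#' @param rest_after_s trailing rest, s
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_long = 20, n_short = 2, fs = 3.9062,
                       design = NULL, subject_age = 20,
                       activation_hbo_amp = 1.0,
                       activation_hbr_amp = -1 / 3,
                       hbr_delay_s = 1,
                       global_lf_band = c(0.01, 0.15),
                       global_lag_range_s = 5,
                       global_amp = 4.75,
                       cardiac_freq = 1.0, cardiac_amp = 0.45,
                       resp_freq = 0.3, resp_amp = 0.2,
                       drift_amp = 0.6,
                       hbr_physio_scale = 0.35,
                       noise_sd = 5e-4,
                       motion_events = list(),
                       bad_channels = integer(),
                       rest_before_s = 15, rest_after_s = 15) {
  if (is.null(design)) {
    design <- stimulus_design(onsets = rest_before_s + 25 * (0:9),
                              task_duration = 10, rest_duration = 15)
  }
  if (!(activation_hbr_amp < 0 && activation_hbo_amp > 0)) {
    stop("sim_config: activation amplitudes must satisfy hbr < 0 < hbo")
  }
  if (any(c(cardiac_freq, resp_freq, global_lf_band) >= fs / 2)) {
    stop("sim_config: all component frequencies must be below Nyquist")
  }
  structure(
    list(n_long = n_long, n_short = n_short, fs = fs, design = design,
         subject_age = subject_age,
         activation_hbo_amp = activation_hbo_amp,
         activation_hbr_amp = activation_hbr_amp,
         hbr_delay_s = hbr_delay_s,
         global_lf_band = global_lf_band,
         global_lag_range_s = global_lag_range_s,
         global_amp = global_amp,
         cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
         resp_freq = resp_freq, resp_amp = resp_amp,
         drift_amp = drift_amp,
         hbr_physio_scale = hbr_physio_scale,
         noise_sd = noise_sd,
         motion_events = motion_events,
         bad_channels = as.integer(bad_channels),
         rest_before_s = rest_before_s, rest_after_s = rest_after_s),
    class = "sim_config"
  )
}

# band-limited unit-variance Gaussian noise via spectral masking
bandlimited_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  f <- seq(0, fs - fs / n, length.out = n)
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  mask <- as.numeric(f >= band[1] & f <= band[2])
  y <- Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(y)
  y / s
}

#' Simulate a dual-wavelength recording with ground truth
#'
#' @param cfg a [sim_config()]
#' @param seed integer seed; all randomness is derived from it
#' @return list with elements `recording` (a [raw_recording()]) and `truth`
#'   (ground-truth components: per-channel true amplitudes, global-LF lags,
#'   bad channels, artifact log, and the latent component time series)
#' @export
simulate_recording <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  fs <- cfg$fs
  layout <- default_layout(cfg$n_long, cfg$n_short)
  design <- cfg$design
  dur_s <- max(design$onsets) + design$task_duration + cfg$rest_after_s
  n <- as.integer(round(dur_s * fs))
  nc <- n_channels(layout)
  t <- (seq_len(n) - 1) / fs

  bad <- cfg$bad_channels
  if (any(bad < 1 | bad > nc)) stop("simulate_recording: bad channel index out of range")

  # -- neural response, ROI long channels only ---------------------------
  hrf <- canonical_hrf(fs)
  r_hbo <- task_regressor(design, fs, n, hrf = hrf)
  r_hbr <- task_regressor(design, fs, n, hrf = hrf,
                          onset_shift_s = cfg$hbr_delay_s)
  # normalize so the noiseless block-averaged task-window contrast equals 1
  norm_contrast <- function(r) {
    ba <- block_windows_mean(r, fs, design$onsets)
    contr <- mean(ba$dur) - mean(ba$pre)
    if (contr <= 0) stop("simulate_recording: degenerate design")
    r / contr
  }
  r_hbo <- norm_contrast(r_hbo)
  r_hbr <- norm_contrast(r_hbr)

  roi <- layout$roi_channels
  true_hbo <- numeric(nc); true_hbr <- numeric(nc)
  true_hbo[roi] <- cfg$activation_hbo_amp
  true_hbr[roi] <- cfg$activation_hbr_amp

  # -- latent physiological components -----------------------------------
  pad <- as.integer(ceiling(cfg$global_lag_range_s * fs)) + 1L
  master_ext <- 0.55 * sin(2 * pi * 0.1 * ((seq_len(n + 2 * pad) - 1) / fs)) +
    0.45 * bandlimited_noise(n + 2 * pad, fs, cfg$global_lf_band)
  lags_s <- stats::runif(nc, -cfg$global_lag_range_s, cfg$global_lag_range_s)
  lag_samp <- as.integer(round(lags_s * fs))
  lags_s <- lag_samp / fs                    # quantized to the sample grid

  cardiac <- sin(2 * pi * cfg$cardiac_freq * t +
                   stats::runif(1, 0, 2 * pi))
  resp <- sin(2 * pi * cfg$resp_freq * t + stats::runif(1, 0, 2 * pi))
  drift <- seq(-0.5, 0.5, length.out = n)

  hbo <- matrix(0, n, nc); hbr <- matrix(0, n, nc)
  for (ch in seq_len(nc)) {
    # channel j sees the master global series delayed by lag_j
    gl <- master_ext[pad + seq_len(n) - lag_samp[ch]]
    card <- if (ch %in% bad) 0 else cfg$cardiac_amp * cardiac
    ch_gain <- stats::runif(1, 0.8, 1.2)     # spatial weighting of systemics
    sys_hbo <- cfg$global_amp * ch_gain * gl + card +
      cfg$resp_amp * resp + cfg$drift_amp * drift
    hbo[, ch] <- true_hbo[ch] * r_hbo + sys_hbo
    hbr[, ch] <- true_hbr[ch] * r_hbr + cfg$hbr_physio_scale * sys_hbo
  }

  conc <- conc_series(hbo, hbr, fs, layout)
  od <- concentration_to_od(conc, cfg$subject_age)

  # -- motion artifacts (in OD space) ------------------------------------
  artifact_log <- list()
  if (length(cfg$motion_events)) {
    od <- inject_motion(od, cfg$motion_events)
    artifact_log <- cfg$motion_events
  }

  # -- forward to intensity with sensor noise ----------------------------
  I0 <- 1
  intensity <- array(0, c(n, nc, 2))
  for (ch in seq_len(nc)) {
    sdn <- cfg$noise_sd * if (ch %in% bad) 10 else 1
    for (w in 1:2) {
      clean <- I0 * exp(-od$od[, ch, w])
      noisy <- clean + stats::rnorm(n, 0, sdn)
      intensity[, ch, w] <- pmax(noisy, I0 * 1e-3)   # keep strictly positive
    }
  }

  rec <- raw_recording(intensity, fs, layout, design, cfg$subject_age)
  truth <- list(
    true_hbo = true_hbo, true_hbr = true_hbr,
    channel_lags_s = lags_s,
    bad_channels = bad,
    artifacts = artifact_log,
    components = list(neural_hbo = r_hbo, neural_hbr = r_hbr,
                      global_lf = master_ext[pad + seq_len(n)],
                      cardiac = cardiac, resp = resp, drift = drift),
    config = cfg
  )
  list(recording = rec, truth = truth)
}

# shared helper: per-block pre/dur window means of a single series
block_windows_mean <- function(x, fs, onsets, pre_window = c(-4, 0),
                               dur_window = c(5, 15)) {
  n <- length(x)
  pre <- numeric(0); dur <- numeric(0); kept <- integer(0)
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    ip <- time_to_index(on + pre_window[1], fs):(time_to_index(on + pre_window[2], fs) - 1L)
    id <- time_to_index(on + dur_window[1], fs):(time_to_index(on + dur_window[2], fs) - 1L)
    if (min(ip) < 1 || max(id) > n) next
    pre <- c(pre, mean(x[ip])); dur <- c(dur, mean(x[id]))
    kept <- c(kept, k)
  }
  list(pre = pre, dur = dur, blocks = kept)
}

#' Inject motion artifacts into an optical-density series
#'
#' Spikes add a Gaussian bump (FWHM `width_s`) and baseline shifts add a
#' step from the event time onward; both are scaled to `amplitude` multiples
#' of the channel's pre-event OD standard deviation, applied to every
#' channel and wavelength (head motion is global).
#'
#' @param od an [od_series()]
#' @param events list of [artifact_event()]s, all within the recording
#' @return an [od_series()] with artifacts added
#' @export
inject_motion <- function(od, events) {
  stopifnot(inherits(od, "od_series"))
  if (length(events) == 0) return(od)
  n <- dim(od$od)[1]
  dur_s <- n / od$fs
  t <- (seq_len(n) - 1) / od$fs
  out <- od$od
  for (ev in events) {
    stopifnot(inherits(ev, "artifact_event"))
    if (ev$time_s < 0 || ev$time_s > dur_s) {
      stop("inject_motion: event at ", ev$time_s, " s is outside the recording")
    }
    for (ch in seq_len(dim(out)[2])) {
      for (w in 1:2) {
        s <- stats::sd(od$od[, ch, w])
        if (s == 0) s <- 1e-6
        if (ev$kind == "spike") {
          sig <- ev$width_s / 2.355           # FWHM -> gaussian sigma
          bump <- ev$amplitude * s * exp(-(t - ev$time_s)^2 / (2 * sig^2))
          out[, ch, w] <- out[, ch, w] + bump
        } else {
          step <- ev$amplitude * s * as.numeric(t >= ev$time_s)
          out[, ch, w] <- out[, ch, w] + step
        }
      }
    }
  }
  od_series(out, od$fs, od$layout)
}
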