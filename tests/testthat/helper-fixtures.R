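# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the suite stays fast.

FS <- 3.9062

small_sim <- function(n_long = 6, n_short = 2, ...) {
  sim_config(n_long = n_long, n_short = n_short, ...)
}

# a clean dual-wavelength recording with cardiac in every channel: used by
# the channel-quality tests
cardiac_recording <- function(n_channels = 5, dur_s = 90, fs = FS,
                              drop_cardiac = integer(), seed = 1) {
  set.seed(seed)
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  lay <- default_layout(n_channels, 0)
  intensity <- array(0, c(n, n_channels, 2))
  card <- sin(2 * pi * 1.1 * t)
  for (ch in seq_len(n_channels)) {
    has_card <- !(ch %in% drop_cardiac)
    for (w in 1:2) {
      x <- 0.02 * card * has_card + 0.002 * rnorm(n)
      intensity[, ch, w] <- 1 + x - min(0, min(1 + x) - 1e-3)
    }
  }
  stim <- stimulus_design(onsets = c(20, 45), task_duration = 10,
                          rest_duration = 15)
  raw_recording(intensity, fs, lay, stim, subject_age = 25)
}

# spike-laden series: task-band oscillation + weak cardiac + sensor noise,
# corrupted by sharp one-sample motion spikes of `amplitude_sd` channel SDs
spike_fixture <- function(seed, n = 977, fs = FS, n_spikes = 1,
                          amplitude_sd = 10) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / fs
  clean <- 0.3 * sin(2 * pi * 0.04 * t) + 0.1 * sin(2 * pi * 1 * t) +
    0.05 * rnorm(n)
  corrupted <- clean
  ks <- sample(80:(n - 80), n_spikes)
  amp <- amplitude_sd * sd(clean)
  corrupted[ks] <- corrupted[ks] + amp * sample(c(-1, 1), n_spikes,
                                                replace = TRUE)
  list(clean = clean, corrupted = corrupted, spikes = ks, spike_amp = amp)
}

# lagged-global OD fixture: shared band-limited master, per-channel lags
# within the search window, small independent residuals
global_od_fixture <- function(seed, n_channels = 8, n = 977, fs = FS,
                              resid_sd = 0.1, max_lag_samples = 9) {
  set.seed(seed)
  lay <- default_layout(n_channels, 0)
  pad <- 40
  master <- optoflow:::bandlimited_noise(n + 2 * pad, fs, c(0.01, 0.15))
  lags <- sample(-max_lag_samples:max_lag_samples, n_channels, replace = TRUE)
  od <- array(0, c(n, n_channels, 2))
  resid <- matrix(rnorm(n * n_channels, sd = resid_sd), n, n_channels)
  for (ch in seq_len(n_channels)) for (w in 1:2) {
    od[, ch, w] <- master[pad + seq_len(n) - lags[ch]] + resid[, ch]
  }
  list(od = od_series(od, fs, lay), lags = lags,
       master = master[pad + seq_len(n)], resid = resid)
}

# variance within a frequency band by periodogram integration
band_power <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  sum(p[f >= band[1] & f <= band[2]])
}

# brute-force step-up BH oracle, written independently of bh_adjust()
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}
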