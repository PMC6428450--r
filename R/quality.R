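# Automated channel exclusion: coefficient of variation on raw intensity,
# and the windowed scalp-coupling-index / cardiac-power rule.

#' Coefficient of variation of a raw intensity series
#'
#' `CV(%) = 100 * sd(x) / mean(x)` with the sample (n-1) standard
#' deviation. Defined on raw intensity only: on optical density the mean is
#' near zero and the ratio degenerates.
#'
#' @param x numeric raw intensity series, length >= 2, positive mean
#' @return CV in percent
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2) stop("coefficient_of_variation: need at least 2 samples")
  m <- mean(x)
  if (m <= 0) stop("coefficient_of_variation: degenerate signal (mean <= 0)")
  100 * stats::sd(x) / m
}

#' Channel exclusion by coefficient of variation
#'
#' Computes the CV per channel and wavelength on the raw intensities; the
#' channel statistic is the maximum over the two wavelengths (the
#' conservative aggregation), and channels with CV strictly above
#' `threshold_percent` are excluded.
#'
#' @param rec a [raw_recording()]
#' @param threshold_percent exclusion threshold (default 7.5)
#' @return a `quality_report`: data.frame with per-channel `cv_percent` and
#'   `excluded`, plus attributes recording method and threshold
#' @export
cv_exclusion <- function(rec, threshold_percent = 7.5) {
  stopifnot(inherits(rec, "raw_recording"))
  nc <- n_channels(rec$layout)
  cv <- vapply(seq_len(nc), function(ch) {
    max(coefficient_of_variation(rec$intensity[, ch, 1]),
        coefficient_of_variation(rec$intensity[, ch, 2]))
  }, numeric(1))
  rep <- data.frame(channel = seq_len(nc), cv_percent = cv,
                    excluded = cv > threshold_percent)
  structure(rep, class = c("quality_report", "data.frame"),
            method = "cv", threshold = threshold_percent)
}

# zero-phase band-pass used for the coupling index; order-1 Butterworth
# applied forward-backward with full reflection padding (short windows)
sci_bandpass <- function(x, fs, band, order = 1) {
  hi <- min(band[2], 0.999 * fs / 2)
  bf <- signal::butter(order, c(band[1], hi) / (fs / 2), type = "pass")
  np <- length(x)
  xp <- c(rev(x), x, rev(x))
  y <- signal::filtfilt(bf, xp)
  y[(np + 1):(2 * np)]
}

#' Scalp coupling index of one window
#'
#' Zero-lag Pearson correlation of the two wavelengths of one channel after
#' zero-phase band-passing to the cardiac band. A well-coupled optode pair
#' shares the cardiac pulsation at both wavelengths, driving the
#' correlation toward 1.
#'
#' @param window_w1,window_w2 equal-length windows from the two wavelengths
#' @param fs sampling rate (Hz)
#' @param band cardiac band in Hz (default 0.8-1.95)
#' @return correlation in `[-1, 1]`, or `NA` for a zero-variance window
#'   (counted as failing by the exclusion rule)
#' @export
sci <- function(window_w1, window_w2, fs, band = c(0.8, 1.95)) {
  if (length(window_w1) != length(window_w2)) {
    stop("sci: windows must have equal length")
  }
  f1 <- sci_bandpass(window_w1, fs, band)
  f2 <- sci_bandpass(window_w2, fs, band)
  if (stats::sd(f1) == 0 || stats::sd(f2) == 0) return(NA_real_)
  stats::cor(f1, f2)
}

#' Peak cardiac cross-spectral power of one window
#'
#' Each window is quadratically detrended (removing the local low-frequency
#' systemic trend that otherwise dominates a 3 s window's energy), then the
#' unbiased cross-correlation of the two wavelength windows is normalized
#' by the windows' energies so the statistic is scale-free (a shared unit-
#' correlation oscillation yields a cross-correlation of amplitude ~1). The
#' normalized cross-correlation is Hamming-windowed, zero-padded and
#' Fourier-transformed; the returned value is the peak squared amplitude
#' within the cardiac band. Coupled cardiac pulsation concentrates the
#' cross-correlation's energy at the heart rate, giving values near 1;
#' independent noise stays well below 0.1.
#'
#' @param window_w1,window_w2 equal-length windows from the two wavelengths
#' @param fs sampling rate (Hz)
#' @param band cardiac band in Hz
#' @param nfft FFT length (zero-padded)
#' @return peak normalized power in `[0, ~1]`, `NA` for zero-variance input
#' @export
cardiac_power <- function(window_w1, window_w2, fs, band = c(0.8, 1.95),
                          nfft = 256) {
  m <- length(window_w1)
  if (m != length(window_w2)) stop("cardiac_power: windows must have equal length")
  tt <- seq_len(m)
  basis <- cbind(1, tt, tt^2)
  window_w1 <- stats::lm.fit(basis, window_w1)$residuals
  window_w2 <- stats::lm.fit(basis, window_w2)$residuals
  e1 <- sum(window_w1^2); e2 <- sum(window_w2^2)
  if (e1 == 0 || e2 == 0) return(NA_real_)
  lags <- -(m - 1):(m - 1)
  xc <- vapply(lags, function(k) {
    s <- if (k >= 0) sum(window_w1[1:(m - k)] * window_w2[(1 + k):m])
         else sum(window_w1[(1 - k):m] * window_w2[1:(m + k)])
    s / (m - abs(k))
  }, numeric(1))
  xc <- xc * m / sqrt(e1 * e2)
  L <- length(xc)
  h <- 0.54 - 0.46 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  F <- stats::fft(c(xc * h, rep(0, nfft - L)))
  amp <- Mod(F) / (sum(h) / 2)          # coherent-gain normalized amplitude
  f <- (0:(nfft - 1)) * fs / nfft
  sel <- f >= band[1] & f <= band[2]
  max(amp[sel]^2) / 4
}

#' Windowed SCI/cardiac-power channel exclusion
#'
#' Splits each channel's optical density (by default) into non-overlapping
#' windows of `window_s` seconds (the trailing partial window is dropped);
#' a window passes when `sci >= sci_thresh` AND `cardiac_power >=
#' power_thresh`; the channel is excluded when the fraction of passing
#' windows falls below `accept_fraction`.
#'
#' @param rec a [raw_recording()]
#' @param sci_thresh SCI acceptance threshold (default 0.7)
#' @param power_thresh cardiac-power acceptance threshold (default 0.1)
#' @param window_s window length in seconds (default 3)
#' @param accept_fraction minimum fraction of passing windows (default 0.8)
#' @param band cardiac band in Hz
#' @param on `"od"` (default) to evaluate on optical density, `"raw"` for
#'   mean-centered raw intensity
#' @return a `quality_report` data.frame with per-channel
#'   `fraction_windows_ok`, `excluded`, and per-window statistics in the
#'   `windows` attribute
#' @export
phoebe_exclusion <- function(rec, sci_thresh = 0.7, power_thresh = 0.1,
                             window_s = 3, accept_fraction = 0.8,
                             band = c(0.8, 1.95), on = c("od", "raw")) {
  stopifnot(inherits(rec, "raw_recording"))
  on <- match.arg(on)
  x <- if (on == "od") intensity_to_od(rec)$od else {
    arr <- rec$intensity
    for (ch in seq_len(dim(arr)[2])) for (w in 1:2) {
      arr[, ch, w] <- arr[, ch, w] - mean(arr[, ch, w])
    }
    arr
  }
  n <- dim(x)[1]
  wlen <- as.integer(round(window_s * rec$fs))
  nwin <- n %/% wlen
  if (nwin < 2) stop("phoebe_exclusion: recording shorter than two windows")
  nc <- dim(x)[2]
  frac <- numeric(nc)
  sci_mat <- matrix(NA_real_, nwin, nc)
  pow_mat <- matrix(NA_real_, nwin, nc)
  for (ch in seq_len(nc)) {
    ok <- logical(nwin)
    for (k in seq_len(nwin)) {
      idx <- ((k - 1) * wlen + 1):(k * wlen)
      s <- sci(x[idx, ch, 1], x[idx, ch, 2], rec$fs, band)
      p <- cardiac_power(x[idx, ch, 1], x[idx, ch, 2], rec$fs, band)
      sci_mat[k, ch] <- s; pow_mat[k, ch] <- p
      ok[k] <- !is.na(s) && !is.na(p) && s >= sci_thresh && p >= power_thresh
    }
    frac[ch] <- mean(ok)
  }
  rep <- data.frame(channel = seq_len(nc), fraction_windows_ok = frac,
                    excluded = frac < accept_fraction)
  structure(rep, class = c("quality_report", "data.frame"),
            method = "phoebe",
            thresholds = list(sci = sci_thresh, power = power_thresh,
                              accept_fraction = accept_fraction,
                              window_s = window_s, band = band),
            windows = list(sci = sci_mat, power = pow_mat))
}

#' Excluded channels from a quality report
#' @param report a `quality_report`
#' @return integer channel indices
#' @export
excluded_channels <- function(report) report$channel[report$excluded]
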