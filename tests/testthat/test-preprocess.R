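# OD conversion, DPF model, modified Beer-Lambert round trips, wavelet
# motion correction and the three band-pass filters.

test_that("intensity to OD inverts an exponential attenuation model", {
  lay <- default_layout(2, 0)
  n <- 120
  x <- 0.05 * sin(2 * pi * 0.1 * (1:n) / FS)
  intensity <- array(0, c(n, 2, 2))
  for (ch in 1:2) for (w in 1:2) intensity[, ch, w] <- 2 * exp(-x)
  rec <- raw_recording(intensity, FS, lay, stimulus_design(5, 5, 5), 25)
  od <- intensity_to_od(rec)
  # exact inversion up to the mean-referencing constant
  expect_lt(max(abs(od$od[, 1, 1] - (x + log(mean(exp(-x)))))), 1e-12)
  expect_lt(max(abs(od$od[, 1, 1] - (x - mean(x)))), 1e-3)

  # constant intensity -> zero OD; doubling intensity leaves OD unchanged
  const <- rec; const$intensity[] <- 3
  expect_lt(max(abs(intensity_to_od(const)$od)), 1e-12)
  doubled <- rec; doubled$intensity <- rec$intensity * 2
  expect_equal(intensity_to_od(doubled)$od, od$od, tolerance = 1e-12)
})

test_that("age-dependent DPF matches the published general equation", {
  # independent evaluation of the polynomial, written out longhand
  ref <- function(l, a) {
    223.3 + 0.05624 * a^0.8493 - 5.723e-7 * l^3 + 0.001245 * l^2 -
      0.9025 * l
  }
  expect_equal(dpf_age(760, 25), ref(760, 25))
  expect_equal(dpf_age(850, 25), ref(850, 25))
  expect_equal(dpf_age(760, 25), 6.1516, tolerance = 1e-4)
  # monotone in age; longer wavelength has the shorter path factor
  for (l in c(760, 850)) expect_gt(dpf_age(l, 40), dpf_age(l, 10))
  for (a in c(20, 40, 60)) expect_gt(dpf_age(760, a), dpf_age(850, a))
  expect_error(dpf_age(760, -1), "age")
})

test_that("Beer-Lambert forward/backward conversion round-trips", {
  lay <- default_layout(3, 1)
  set.seed(5)
  for (i in 1:10) {
    conc <- conc_series(matrix(rnorm(60 * 4), 60), matrix(rnorm(60 * 4), 60),
                        FS, lay)
    od <- concentration_to_od(conc, age_years = 30)
    back <- od_to_concentration(od, age_years = 30)
    denom <- max(abs(conc$hbo), abs(conc$hbr))
    expect_lt(max(abs(back$hbo - conc$hbo), abs(back$hbr - conc$hbr)) / denom,
              1e-10)
  }
  # zero maps to zero, scaling is linear
  z <- conc_series(matrix(0, 10, 4), matrix(0, 10, 4), FS, lay)
  expect_true(all(concentration_to_od(z, 30)$od == 0))
  c1 <- conc_series(matrix(1, 10, 4), matrix(0.5, 10, 4), FS, lay)
  od1 <- concentration_to_od(c1, 30)
  b2 <- od_to_concentration(od_series(2 * od1$od, FS, lay), 30)
  expect_equal(b2$hbo, 2 * c1$hbo, tolerance = 1e-10)
})

test_that("pure HbO step produces the closed-form OD wavelength ratio", {
  lay <- default_layout(1, 0)
  conc <- conc_series(matrix(1, 10, 1), matrix(0, 10, 1), FS, lay)
  od <- concentration_to_od(conc, 30)
  ext <- extinction_table(c(760, 850))
  expected <- (ext$eps_hbo[2] * dpf_age(850, 30)) /
    (ext$eps_hbo[1] * dpf_age(760, 30))
  expect_equal(od$od[1, 1, 2] / od$od[1, 1, 1], expected, tolerance = 1e-12)
})

test_that("the periodized DWT reconstructs exactly", {
  set.seed(6)
  for (wf in c("db2", "db4")) {
    x <- rnorm(256)
    w <- dwt_periodic(x, wf)
    expect_lt(max(abs(idwt_periodic(w) - x)), 1e-9)
  }
  expect_error(dwt_periodic(rnorm(100)), "power of two")
})

test_that("IQR wavelet correction removes spikes and preserves clean signal", {
  # removal is strong on average across fixtures; individual spikes can
  # leave a modest residue when their mid-level coefficients fall inside
  # a signal-widened fence
  surviving <- vapply(31:38, function(seed) {
    fx <- spike_fixture(seed = seed)
    out <- wavelet_motion_correct(fx$corrupted)
    expect_gt(cor(out, fx$clean), cor(fx$corrupted, fx$clean))
    abs(out - fx$clean)[fx$spikes] / fx$spike_amp
  }, numeric(1))
  expect_lt(mean(surviving), 0.10)
  expect_lt(max(surviving), 0.25)

  # nothing to remove on a clean band-limited signal
  t <- (0:976) / FS
  clean <- sin(2 * pi * 0.04 * t) + 0.5 * sin(2 * pi * 1 * t)
  expect_gt(cor(wavelet_motion_correct(clean), clean), 0.99)
})

test_that("IQR wavelet correction is near-idempotent", {
  fx <- spike_fixture(seed = 32)
  once <- wavelet_motion_correct(fx$corrupted)
  twice <- wavelet_motion_correct(once)
  expect_gt(cor(once, twice), 0.995)
})

test_that("kurtosis correction passes Gaussian coefficients untouched and trims heavy tails", {
  set.seed(33)
  g <- rnorm(977)   # white noise: near-Gaussian coefficients at all levels
  expect_gt(cor(kurtosis_wavelet_motion_correct(g), g), 0.99)

  fx <- spike_fixture(seed = 34, n_spikes = 5)
  out <- kurtosis_wavelet_motion_correct(fx$corrupted, cycle_spins = 1)
  w <- optoflow:::dwt_series(out, "db2", NULL)
  pooled <- unlist(w$dec$details)
  expect_lte(optoflow:::moment_kurtosis(pooled), 3.3 + 0.2)
})

test_that("the kurtosis rule corrects at least as aggressively as the IQR rule", {
  for (seed in 41:46) {
    fx <- spike_fixture(seed = seed, n_spikes = 3)
    mc1 <- wavelet_motion_correct(fx$corrupted)
    mc2 <- kurtosis_wavelet_motion_correct(fx$corrupted)
    expect_gte(1 - cor(mc2, fx$corrupted), 1 - cor(mc1, fx$corrupted))
  }
})

test_that("band-pass filters have unit passband and strong stopband", {
  t <- (0:976) / FS
  mid <- 200:778
  tone_in <- sin(2 * pi * 0.04 * t)
  tone_out <- sin(2 * pi * 1 * t)
  for (f in list(bandpass_bw_sequential, bandpass_bw_direct)) {
    expect_gte(max(abs(f(tone_in, FS)[mid])), 0.95)
    expect_lte(max(abs(f(tone_in, FS)[mid])), 1.02)
    expect_lt(max(abs(f(tone_out, FS)[mid])), 0.01)
  }
  y <- bandpass_fft_trapezoid(tone_in, FS)
  expect_equal(max(abs(y[mid])), 1, tolerance = 2e-2)
  # hard stopband of the exact circular variant (bin-centered tone)
  f_oob <- round(0.25 * 977 / FS) * FS / 977
  y2 <- bandpass_fft_trapezoid(sin(2 * pi * f_oob * t), FS, pad = FALSE)
  expect_lt(max(abs(y2)), 1e-6)
  expect_true(all(bandpass_fft_trapezoid(rep(0, 977), FS) == 0))
  expect_error(bandpass_bw_direct(tone_in, FS, lo = 0.01, hi = 3), "band")
})

test_that("all three filters are zero-phase on an in-band tone", {
  t <- (0:976) / FS
  tone <- sin(2 * pi * 0.04 * t)
  for (f in list(bandpass_bw_sequential, bandpass_bw_direct,
                 bandpass_fft_trapezoid)) {
    y <- f(tone, FS)
    cc <- crosscorr_optimal_lag(tone, y, FS, max_lag_s = 3)
    expect_lte(abs(cc$lag_samples), 1)
  }
})

test_that("the two Butterworth variants agree on a pure in-band tone", {
  t <- (0:976) / FS
  tone <- sin(2 * pi * 0.05 * t)
  a <- bandpass_bw_sequential(tone, FS)
  b <- bandpass_bw_direct(tone, FS)
  expect_gt(cor(a, b), 1 - 1e-5)
  expect_lt(max(abs(a - b)[200:778]), 0.02)
})

test_that("filter magnitudes match the transfer-function oracle", {
  # oracle: evaluate |H| of the designed filters directly; filtfilt
  # squares the magnitude
  fs <- FS
  freqs <- c(0.04, 0.1, 0.5, 1.0)
  lp <- signal::butter(3, 0.2 / (fs / 2), "low")
  hp <- signal::butter(3, 0.01 / (fs / 2), "high")
  H <- function(flt, f) Mod(signal::freqz(flt$b, flt$a, 2 * pi * f / fs)$h)
  expected <- (H(lp, freqs) * H(hp, freqs))^2
  n <- 40000  # long record so edge effects are negligible
  t <- (0:(n - 1)) / fs
  for (i in seq_along(freqs)) {
    y <- bandpass_bw_sequential(sin(2 * pi * freqs[i] * t), fs)
    gain <- max(abs(y[10000:30000]))
    expect_equal(gain, expected[i], tolerance = 1e-4)
  }
})
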