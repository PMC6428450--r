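# Adaptive reference regression, short-separation and PCA de-noising, the
# lag-adjusted global average, and the correlation-threshold null.

test_that("LMS filter converges onto a scaled reference", {
  set.seed(51)
  ref <- as.numeric(arima.sim(list(ar = 0.9), 4000))
  target <- 2.0 * ref
  res <- adaptive_filter_regress(target, ref)
  burn <- 500
  expect_lt(sqrt(mean(res$residual[-(1:burn)]^2)),
            0.05 * sqrt(mean(target[-(1:burn)]^2)))

  # orthogonal reference leaves the target alone
  noise <- rnorm(4000)
  res2 <- adaptive_filter_regress(noise, ref)
  expect_gt(cor(res2$residual, noise), 0.95)

  # mu = 0: no adaptation at all
  res3 <- adaptive_filter_regress(target, ref, mu = 0)
  expect_identical(res3$residual, target)
  expect_error(adaptive_filter_regress(target, rep(1, 4000)), "degenerate")
})

test_that("short-separation regression removes the shared systemic part", {
  set.seed(52)
  n <- 977
  lay <- default_layout(4, 1)
  systemic <- optoflow:::bandlimited_noise(n, FS, c(0.01, 0.15))
  neural <- matrix(rnorm(n * 4, sd = 0.3), n)
  hbo <- cbind(neural + 0.8 * systemic, systemic + 0.02 * rnorm(n))
  hbr <- -0.3 * hbo
  conc <- conc_series(hbo, hbr, FS, lay)
  res <- ssd_denoise(conc)
  for (ch in 1:4) {
    expect_lt(abs(cor(res$conc$hbo[, ch], systemic)), 0.2)
    # hbr altered too, even though its mixture is just a scaled copy
    expect_false(identical(res$conc$hbr[, ch], conc$hbr[, ch]))
  }
  # short channel passed through
  expect_identical(res$conc$hbo[, 5], conc$hbo[, 5])

  # uncorrelated short channel: long channels essentially unchanged
  hbo2 <- cbind(neural, rnorm(n))
  conc2 <- conc_series(hbo2, -0.3 * hbo2, FS, lay)
  res2 <- ssd_denoise(conc2)
  for (ch in 1:4) expect_gt(cor(res2$conc$hbo[, ch], hbo2[, ch]), 0.95)

  no_short <- conc_series(neural, -0.3 * neural, FS, default_layout(4, 0))
  expect_error(ssd_denoise(no_short), "short channel")
})

test_that("first-PC removal captures rank-1 global structure", {
  set.seed(53)
  n <- 600
  lay <- default_layout(6, 0)
  global <- optoflow:::bandlimited_noise(n, FS, c(0.01, 0.15))
  weights <- runif(6, 0.5, 1.5)
  od <- array(0, c(n, 6, 2))
  for (ch in 1:6) for (w in 1:2) {
    od[, ch, w] <- weights[ch] * global + 1e-3 * rnorm(n)
  }
  ods <- od_series(od, FS, lay)
  res <- pca_denoise(ods)
  for (ch in 1:6) {
    expect_lt(var(res$od$od[, ch, 1]) / var(od[, ch, 1]), 0.01)
  }
  # the removed component tracks the plain channel mean
  expect_gt(abs(cor(res$components[[1]][, 1], rowMeans(od[, , 1]))), 0.9)
  # residual orthogonal to the removed time course
  for (ch in c(1, 4)) {
    expect_lt(abs(cor(res$od$od[, ch, 1] - mean(res$od$od[, ch, 1]),
                      res$components[[1]][, 1])), 1e-8)
  }
  expect_error(pca_denoise(ods, n_components = 6), "more channels")
})

test_that("lag search finds constructed shifts and honors its window", {
  set.seed(54)
  n <- 977
  x <- optoflow:::bandlimited_noise(n + 60, FS, c(0.01, 0.15))
  shift <- round(2.0 * FS)
  y <- x[seq_len(n)]
  x2 <- x[shift + seq_len(n)]   # y = x2 delayed by +2 s
  cc <- crosscorr_optimal_lag(x2, y, FS)
  expect_equal(cc$lag_samples, shift, tolerance = 1)
  expect_gt(cc$r, 0.99)

  same <- crosscorr_optimal_lag(y, y, FS)
  expect_identical(same$lag_samples, 0L)
  expect_equal(same$r, 1)

  # true shift outside the window: the in-window optimum is reported and
  # its correlation falls short of true alignment
  shift7 <- round(7 * FS)
  y7 <- x[seq_len(n)]
  x7 <- x[shift7 + seq_len(n)]
  cc7 <- crosscorr_optimal_lag(x7, y7, FS, max_lag_s = 5)
  expect_lte(abs(cc7$lag_s), 5)
  expect_lt(cc7$r, cor(x7, x7))
  expect_error(crosscorr_optimal_lag(rep(1, n), y, FS), "degenerate")
})

test_that("delay-corrected global average removes the lagged global band", {
  fx <- global_od_fixture(seed = 55)
  res <- lagged_global_average(fx$od)
  for (ch in seq_len(n_channels(fx$od$layout))) {
    removed <- 1 - band_power(res$od$od[, ch, 1], FS, c(0.01, 0.15)) /
      band_power(fx$od$od[, ch, 1], FS, c(0.01, 0.15))
    expect_gte(removed, 0.9)
  }
  diag760 <- res$diagnostics[res$diagnostics$wavelength == 760, ]
  expect_true(all(diag760$n_accepted >= 1))
  expect_true(all(diag760$removed_fraction >= 0))
})

test_that("single channels and independent groups are left alone", {
  set.seed(56)
  n <- 600
  one <- od_series(array(rnorm(n * 2), c(n, 1, 2)), FS, default_layout(1, 0))
  res1 <- lagged_global_average(one)
  expect_identical(res1$od$od, one$od)
  expect_true(all(res1$diagnostics$flag == "no correlated channels"))

  # two groups sharing nothing across groups
  lay <- default_layout(6, 0)
  g1 <- optoflow:::bandlimited_noise(n, FS, c(0.01, 0.15))
  g2 <- optoflow:::bandlimited_noise(n, FS, c(0.01, 0.15))
  od <- array(0, c(n, 6, 2))
  for (ch in 1:3) for (w in 1:2) od[, ch, w] <- g1 + 0.05 * rnorm(n)
  for (ch in 4:6) for (w in 1:2) od[, ch, w] <- g2 + 0.05 * rnorm(n)
  res <- lagged_global_average(od_series(od, FS, lay))
  p <- res$pairs[res$pairs$wavelength == 760, ]
  cross <- p[(p$target <= 3) != (p$partner <= 3), ]
  within <- p[(p$target <= 3) == (p$partner <= 3), ]
  expect_true(all(within$r > 0.37))
  expect_lt(mean(cross$r > 0.37), 0.2)
})

test_that("cleaned independent residuals show no spurious anti-correlation", {
  fx <- global_od_fixture(seed = 57, resid_sd = 0.3)
  res <- lagged_global_average(fx$od)
  nc <- n_channels(fx$od$layout)
  cors <- cor(res$od$od[, , 1])
  expect_gte(mean(cors[lower.tri(cors)]), -0.1)
})

test_that("de-noisers preserve ROI activation within tolerance", {
  # moderate systemic amplitude so the per-channel contrast noise does not
  # swamp the bias this invariant is after
  sim <- simulate_recording(small_sim(n_long = 8, n_short = 2,
                                      global_amp = 1.5), seed = 58)
  rec <- sim$recording
  roi <- rec$layout$roi_channels
  od <- filter_od(intensity_to_od(rec), "bw_seq")
  for (method in c("none", "ssd", "pca", "gloavg")) {
    den <- denoise(od, method, age_years = rec$subject_age)
    for (ch in roi) {
      ba <- block_average(den$conc$hbo[, ch], rec$fs, rec$stimulus$onsets)
      expect_lt(abs((mean(ba$dur) - mean(ba$pre)) - 1), 0.25)
    }
  }
})

test_that("GloAvg and PCA agree on global-dominated data", {
  # zero channel lags: with phase diversity the global is no longer rank-1
  # and PCA (by design) cannot follow it, so agreement is only expected on
  # a synchronous global component
  fx <- global_od_fixture(seed = 59, resid_sd = 0.15, max_lag_samples = 0)
  g <- lagged_global_average(fx$od)
  p <- pca_denoise(fx$od)
  interior <- 60:918   # the LMS global estimate is undefined at the edges
  cors <- vapply(seq_len(n_channels(fx$od$layout)), function(ch) {
    cor(g$od$od[interior, ch, 1], p$od$od[interior, ch, 1])
  }, numeric(1))
  expect_gt(mean(cors), 0.8)
})

test_that("the correlation-threshold null behaves like theory", {
  # zero-lag white noise: the 97.5% point of r ~ 1.96 / sqrt(n)
  thr <- correlation_threshold_simulation(10000, FS, band = NULL,
                                          n_sims = 400, max_lag_s = 0,
                                          quantile_p = 0.975, seed = 2)
  expect_lt(abs(thr - 1.96 / sqrt(10000)) / (1.96 / sqrt(10000)), 0.2)

  # narrower bands inflate the threshold monotonically
  bands <- list(c(0.01, 0.8), c(0.01, 0.15), c(0.01, 0.05))
  thrs <- vapply(bands, function(b) {
    correlation_threshold_simulation(977, FS, band = b, n_sims = 150,
                                     seed = 3)
  }, numeric(1))
  expect_true(all(diff(thrs) > 0))

  # quantile 1 with two simulations is their maximum
  set.seed(4)
  v <- correlation_threshold_simulation(500, FS, band = NULL, n_sims = 2,
                                        quantile_p = 1, seed = 5)
  expect_true(is.finite(v))
  expect_match(attr(v, "flag"), "unstable")
})
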