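# Block metrics, design matrix, prewhitening, robust GLM, BH adjustment,
# activation rules and comparison statistics.

test_that("block averaging honors its windows and drops boundary blocks", {
  fs <- FS
  n <- round(120 * fs)
  onsets <- c(20, 45, 70, 95)
  # constant series: pre == dur == c
  ba <- block_average(rep(3.5, n), fs, onsets)
  expect_true(all(ba$pre == 3.5) && all(ba$dur == 3.5))
  expect_equal(ba$n_dropped, 0)

  # boxcar active exactly 5-15 s post-onset
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (on in onsets) {
    ip <- optoflow:::time_to_index(on + 5, fs):
      (optoflow:::time_to_index(on + 15, fs) - 1)
    x[ip] <- 2
  }
  ba2 <- block_average(x, fs, onsets)
  expect_equal(ba2$pre, rep(0, 4))
  expect_equal(ba2$dur, rep(2, 4), tolerance = 1e-6)

  # first onset too early for its pre window: block dropped
  ba3 <- block_average(x, fs, c(2, onsets))
  expect_equal(ba3$n_dropped, 1)
  expect_equal(length(ba3$pre), 4)
})

test_that("effect-size formulas match hand computations", {
  pre <- c(1, 2, 1, 2); dur <- c(3, 3, 3, 3)
  expect_equal(cohens_d(pre, dur), (3 - 1.5) / sd(pre))
  expect_equal(cnr(pre, dur), 1.5 / sqrt(var(dur) + var(pre)))
  expect_equal(cohens_d(pre, pre), 0)
  expect_equal(cohens_d(-pre, -dur), -cohens_d(pre, dur))
  expect_equal(cnr(pre + 10, dur + 10), cnr(pre, dur))
  expect_equal(cnr(c(1, 1, 2), c(1, 2, 1)), 0)
  expect_error(cohens_d(c(1, 1), dur), "zero pre-window")
})

test_that("ROI maxima follow the species-specific conventions", {
  expect_equal(roi_max_metric(c(0.2, 0.9, 0.5, 0.1), 1:4, "signed_max"), 0.9)
  expect_equal(roi_max_metric(c(-0.3, -0.8), 1:2, "most_negative"), -0.8)
  expect_equal(roi_max_metric(c(0.3, -0.8), 1:2, "abs_max"), -0.8)
  expect_equal(roi_max_metric(c(5, 1), 2, "signed_max"), 1)
  expect_error(roi_max_metric(1:3, integer()), "empty")
  expect_error(roi_max_metric(1:3, 9), "out of range")
})

test_that("the design matrix has the task fundamental and orthogonal derivatives", {
  stim <- stimulus_design(15 + 25 * (0:9))
  n <- 1035
  X <- build_design_matrix(stim, FS, n)
  expect_identical(colnames(X), c("intercept", "main", "deriv1", "deriv2"))
  expect_lt(abs(sum(X[, "main"] * X[, "deriv1"])), 1e-8)
  expect_lt(abs(sum(X[, "main"] * X[, "deriv2"])), 1e-8)

  X2 <- build_design_matrix(stim, FS, n, include_derivatives = FALSE)
  expect_equal(ncol(X2), 2)

  # dominant spectral peak of the main column at 0.04 Hz
  m <- X[, "main"] - mean(X[, "main"])
  p <- Mod(fft(m))^2
  f <- (0:(n - 1)) * FS / n
  peak_f <- f[f > 0.005 & f < 1][which.max(p[f > 0.005 & f < 1])]
  expect_lt(abs(peak_f - 0.04), FS / n)
  expect_error(build_design_matrix(stim, FS, 10), "shorter")
})

test_that("prewhitening selects low orders on white noise and recovers AR(1)", {
  set.seed(61)
  X <- cbind(intercept = 1, main = rnorm(977))
  ords <- replicate(100, prewhiten(rnorm(977), X, 16)$order)
  expect_gte(mean(ords <= 1), 0.9)

  phis <- replicate(30, {
    y <- as.numeric(arima.sim(list(ar = 0.8), 1000))
    prewhiten(y, rbind(X, X[1:23, ]), 16)$ar_coefficients[1]
  })
  expect_lt(max(abs(phis - 0.8)), 0.1)

  # whitened residuals have negligible lag-1 autocorrelation
  y <- as.numeric(arima.sim(list(ar = 0.8), 1000))
  pw <- prewhiten(y, rbind(X, X[1:23, ]), 16)
  r <- lm.fit(pw$X_w, pw$y_w)$residuals
  expect_lt(abs(acf(r, lag.max = 1, plot = FALSE)$acf[2]), 0.1)
})

test_that("robust GLM recovers a known effect and resists outliers", {
  set.seed(62)
  stim <- stimulus_design(15 + 25 * (0:9))
  X <- build_design_matrix(stim, FS, 1035)
  y <- 2 * X[, "main"] + 0.1 * rnorm(1035)
  fit <- robust_glm(y, X)
  expect_equal(fit$beta_main, 2, tolerance = 0.1)
  expect_gt(fit$t_main, 10)

  # gross outliers: robust beta error below plain OLS in most replicates
  wins <- replicate(40, {
    y2 <- 1 * X[, "main"] + 0.2 * rnorm(1035)
    idx <- sample(1035, 50)
    y2[idx] <- y2[idx] + sample(c(-1, 1), 50, TRUE) * 5
    b_rob <- robust_glm(y2, X, prewhiten_errors = FALSE)$beta_main
    b_ols <- qr.coef(qr(X), y2)["main"]
    abs(b_rob - 1) < abs(b_ols - 1)
  })
  expect_gte(mean(wins), 0.8)
  expect_error(robust_glm(y, cbind(X, X[, 2])), "rank")
})

test_that("null type-I error is calibrated and prewhitening beats its absence", {
  set.seed(63)
  stim <- stimulus_design(15 + 25 * (0:9))
  X <- build_design_matrix(stim, FS, 977)
  res <- t(replicate(150, {
    y <- as.numeric(arima.sim(list(ar = 0.8), 977))
    c(pw = robust_glm(y, X)$p, raw = robust_glm(y, X,
                                                prewhiten_errors = FALSE)$p)
  }))
  a_pw <- mean(res[, "pw"] < 0.05)
  a_raw <- mean(res[, "raw"] < 0.05)
  expect_gte(a_pw, 0.015)
  expect_lte(a_pw, 0.11)
  expect_gt(a_raw, a_pw)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.2)
  expect_equal(bh_adjust(p), c(0.05, 0.05, 0.05, 0.05, 0.2))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(64)
  for (i in 1:25) {
    pv <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(pv), bh_oracle(pv))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("activation rules respect significance and sign", {
  glm_res <- data.frame(
    channel = rep(1:4, 2),
    species = rep(c("hbo", "hbr"), each = 4),
    beta_main = c(1, -1, 1, 1, -1, -1, 1, -1),
    q = c(0.01, 0.01, 0.3, 0.01, 0.3, 0.01, 0.01, 0.01))
  dec <- activation_decision(glm_res, alpha = 0.05)
  # ch1: hbo sig+, hbr ns -> oxy only
  expect_true(dec$oxy_active[1]); expect_false(dec$combined_active[1])
  # ch2: hbo sig but beta < 0 -> not oxy; hbr sig- -> deoxy
  expect_false(dec$oxy_active[2]); expect_true(dec$deoxy_active[2])
  # ch3: hbo ns; hbr sig but beta > 0 -> nothing
  expect_false(any(dec$oxy_active[3], dec$deoxy_active[3]))
  # ch4: both significant with canonical signs -> combined
  expect_true(dec$combined_active[4])
  expect_true(all(dec$combined_active == (dec$oxy_active & dec$deoxy_active)))
})

test_that("paired comparisons handle degenerate and null cases", {
  a <- rnorm(16)
  out <- paired_t_bh(list(shift = list(a = a + 1, b = a)))
  expect_lt(out$p_c, 1e-10)
  # single comparison: corrected equals uncorrected
  out2 <- paired_t_bh(list(one = list(a = rnorm(10), b = rnorm(10))))
  expect_equal(out2$p_c, out2$p)

  set.seed(65)
  fam_sig <- replicate(200, {
    fam <- list(c1 = list(a = rnorm(8), b = rnorm(8)),
                c2 = list(a = rnorm(8), b = rnorm(8)))
    any(paired_t_bh(fam)$p_c < 0.05)
  })
  expect_lte(mean(fam_sig), 0.1)
})

test_that("method correlation handles identity, inversion and independence", {
  x <- rnorm(100)
  expect_equal(method_correlation(x, x), 1)
  expect_equal(method_correlation(x, -x), -1)
  set.seed(66)
  rs <- replicate(200, method_correlation(rnorm(1000), rnorm(1000)))
  expect_gte(mean(abs(rs) < 0.1), 0.95)
  expect_error(method_correlation(x, rep(1, 100)), "zero-variance")
})

test_that("the q values never undercut the raw p values", {
  sim <- simulate_recording(small_sim(), seed = 67)
  res <- process_recording(sim$recording, exclude_method = "none",
                           denoise_method = "none")
  g <- res$glm[res$glm$included, ]
  expect_true(all(g$q >= g$p - 1e-12))
  expect_true(all(g$q <= 1))
})
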