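# Low-frequency systemic de-noising: LMS adaptive reference regression
# (used by the short-separation and lag-adjusted global-average methods)
# and first-principal-component removal.

#' Least-mean-squares adaptive reference regression
#'
#' A length-`M` LMS filter tracks the reference's contribution to the
#' target; the residual is returned. With `M = 1` this is a time-varying
#' scalar regression. The filter weights start at zero (so `mu = 0` returns
#' the target untouched) and the step size is specified for a reference
#' internally normalized to standard deviation 10, making convergence
#' scale-free: at the default `mu` the adaptation time constant is roughly
#' 50 samples.
#'
#' @param target numeric series to clean
#' @param reference numeric regressor series, same length, non-degenerate
#' @param mu LMS step size (default 1e-4)
#' @param M filter length in taps (default 1)
#' @param passes number of passes over the series (default 2): the final
#'   weights of each pass initialize the next, so the adaptation transient
#'   of a cold start does not leak reference variance into the residual;
#'   only the last pass's residual is returned. With `mu = 0` the weights
#'   never leave zero and the target is returned untouched regardless.
#' @return list with `residual`, `estimate` (the removed component),
#'   `weights` (final filter taps on the normalized reference), and
#'   `removed_fraction` (variance fraction of the target removed, >= 0 when
#'   the filter converged onto a genuine shared component)
#' @export
adaptive_filter_regress <- function(target, reference, mu = 1e-4, M = 1,
                                    passes = 2) {
  n <- length(target)
  if (length(reference) != n) {
    stop("adaptive_filter_regress: series lengths differ")
  }
  sref <- stats::sd(reference)
  if (sref == 0) stop("adaptive_filter_regress: degenerate reference (zero variance)")
  r <- reference / sref * 10            # scale-free convergence
  w <- numeric(M)
  est <- numeric(n)
  for (pass in seq_len(max(passes, 1))) {
    for (t in seq_len(n)) {
      x <- r[t:max(1, t - M + 1)]
      if (length(x) < M) x <- c(x, numeric(M - length(x)))
      est[t] <- sum(w * x)
      e <- target[t] - est[t]
      w <- w + 2 * mu * e * x
    }
  }
  residual <- target - est
  vt <- stats::var(target)
  rf <- if (vt > 0) 1 - stats::var(residual) / vt else 0
  list(residual = residual, estimate = est, weights = w,
       removed_fraction = rf)
}

# default long -> short assignment: split long channels into halves
# ("hemispheres"), each served by the nearest short channel in index order
default_ssd_assignment <- function(layout) {
  lg <- long_channels(layout)
  sh <- short_channels(layout)
  if (length(sh) == 0) {
    stop("ssd_denoise: layout has no short channels; short-separation ",
         "regression requires at least one")
  }
  grp <- ceiling(seq_along(lg) / (length(lg) / length(sh)))
  grp <- pmin(grp, length(sh))
  stats::setNames(sh[grp], lg)
}

#' Short-separation adaptive-filter de-noising
#'
#' For each long channel and each hemoglobin species independently, the
#' assigned short channel's series is regressed out with
#' [adaptive_filter_regress()]. Operates on concentration changes; both
#' species are filtered separately, so the deoxyhemoglobin series is
#' altered even when only the oxy series shares variance with the
#' reference. Short channels are passed through unchanged.
#'
#' @param conc a [conc_series()]
#' @param assignment named integer vector mapping long-channel index
#'   (names) to short-channel index (values); default: index-halves to the
#'   nearest short channel
#' @param mu,M LMS parameters
#' @return list with `conc` (cleaned [conc_series()]) and `diagnostics`
#'   (per channel/species removed variance fraction)
#' @export
ssd_denoise <- function(conc, assignment = NULL, mu = 1e-4, M = 1) {
  stopifnot(inherits(conc, "conc_series"))
  layout <- conc$layout
  if (is.null(assignment)) assignment <- default_ssd_assignment(layout)
  lg <- long_channels(layout)
  if (!all(as.character(lg) %in% names(assignment))) {
    stop("ssd_denoise: assignment must cover every long channel")
  }
  hbo <- conc$hbo; hbr <- conc$hbr
  diag <- data.frame(channel = rep(lg, 2),
                     species = rep(c("hbo", "hbr"), each = length(lg)),
                     removed_fraction = NA_real_)
  for (ch in lg) {
    sc <- assignment[[as.character(ch)]]
    a <- adaptive_filter_regress(conc$hbo[, ch], conc$hbo[, sc], mu, M)
    b <- adaptive_filter_regress(conc$hbr[, ch], conc$hbr[, sc], mu, M)
    hbo[, ch] <- a$residual; hbr[, ch] <- b$residual
    diag$removed_fraction[diag$channel == ch & diag$species == "hbo"] <- a$removed_fraction
    diag$removed_fraction[diag$channel == ch & diag$species == "hbr"] <- b$removed_fraction
  }
  list(conc = conc_series(hbo, hbr, conc$fs, layout), diagnostics = diag)
}

#' First-principal-component de-noising
#'
#' Spatial PCA of the (filtered) optical-density matrix over long channels,
#' per wavelength; the first `n_components` component time courses are
#' regressed out of every long channel by least squares. The first
#' component of global-physiology-dominated data closely tracks the plain
#' channel mean, so this removes global covariance. Short channels are
#' untouched.
#'
#' @param od an [od_series()] (typically band-passed)
#' @param n_components number of leading components to remove (default 1)
#' @param exclude_short exclude short channels from the PCA and cleaning
#'   (default TRUE)
#' @return list with `od` (cleaned [od_series()]), `diagnostics`
#'   (per-channel removed variance fraction per wavelength) and
#'   `components` (removed time courses per wavelength)
#' @export
pca_denoise <- function(od, n_components = 1, exclude_short = TRUE) {
  stopifnot(inherits(od, "od_series"))
  chans <- if (exclude_short) long_channels(od$layout)
           else seq_len(n_channels(od$layout))
  if (length(chans) <= n_components) {
    stop("pca_denoise: need more channels than components")
  }
  if (dim(od$od)[1] <= length(chans)) {
    stop("pca_denoise: series must be longer than the channel count")
  }
  out <- od$od
  comps <- list()
  diag <- expand.grid(channel = chans, wavelength = od$layout$wavelengths)
  diag$removed_fraction <- NA_real_
  for (w in 1:2) {
    X <- od$od[, chans, w, drop = TRUE]
    Xc <- scale(X, center = TRUE, scale = FALSE)
    pc <- stats::prcomp(Xc, center = FALSE)
    tc <- pc$x[, seq_len(n_components), drop = FALSE]
    comps[[w]] <- tc
    for (i in seq_along(chans)) {
      fit <- stats::lm.fit(cbind(1, tc), X[, i])
      out[, chans[i], w] <- fit$residuals + mean(X[, i])
      diag$removed_fraction[diag$channel == chans[i] &
                              diag$wavelength == od$layout$wavelengths[w]] <-
        1 - stats::var(fit$residuals) / stats::var(X[, i])
    }
  }
  list(od = od_series(out, od$fs, od$layout), diagnostics = diag,
       components = comps)
}

#' Lag-optimized cross-correlation between two series
#'
#' Scans integer-sample lags within `max_lag_s` and returns the lag
#' maximizing the Pearson correlation of the overlapping samples. Positive
#' lag means `y` is delayed with respect to `x` (i.e. `y(t) ~ x(t - lag)`).
#'
#' @param x,y equal-length numeric series
#' @param fs sampling rate (Hz)
#' @param max_lag_s lag window in seconds (default 5)
#' @return list with `lag_s`, `r` (correlation at the optimum), `lag_samples`
#' @export
crosscorr_optimal_lag <- function(x, y, fs, max_lag_s = 5) {
  n <- length(x)
  if (length(y) != n) stop("crosscorr_optimal_lag: lengths differ")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("crosscorr_optimal_lag: degenerate input (zero variance)")
  }
  K <- as.integer(floor(max_lag_s * fs))
  if (n < 2 * K + 2) stop("crosscorr_optimal_lag: series too short for the lag window")
  best <- c(lag = 0L, r = -Inf)
  for (k in -K:K) {
    if (k >= 0) r <- stats::cor(x[1:(n - k)], y[(1 + k):n])
    else r <- stats::cor(x[(1 - k):n], y[1:(n + k)])
    if (!is.na(r) && r > best["r"]) best <- c(lag = k, r = r)
  }
  list(lag_s = unname(best["lag"]) / fs, r = unname(best["r"]),
       lag_samples = as.integer(best["lag"]))
}

# shift y by -lag samples so it aligns with the target; NA at the edges
align_by_lag <- function(y, lag_samples) {
  n <- length(y)
  out <- rep(NA_real_, n)
  idx <- seq_len(n) + lag_samples
  ok <- idx >= 1 & idx <= n
  out[ok] <- y[idx[ok]]
  out
}

#' Delay-corrected global-average de-noising
#'
#' For each target long channel: every other long channel is lag-aligned
#' (optimal lag from [crosscorr_optimal_lag()]); channels whose lag-aligned
#' correlation exceeds `r_thresh` within the `max_lag_s` window are
#' averaged into a per-target global signal, which is regressed out with
#' [adaptive_filter_regress()]. Channels with no accepted partner are
#' returned unchanged and flagged. Operates per wavelength on optical
#' density; lag alignment removes the systemic component's spatial phase
#' differences, which is what prevents the spurious anti-correlations plain
#' global-average regression can induce.
#'
#' @param od an [od_series()] (typically band-passed)
#' @param r_thresh acceptance correlation threshold (default 0.37, an
#'   empirical null quantile; see [correlation_threshold_simulation()])
#' @param max_lag_s lag window (default 5 s)
#' @param exclude_short use long channels only (default TRUE)
#' @param mu,M LMS parameters
#' @return list with `od` (cleaned), `diagnostics` (per channel/wavelength:
#'   accepted partner count, removed variance fraction, flag), and
#'   `pairs` (per-pair lag and correlation tables)
#' @export
lagged_global_average <- function(od, r_thresh = 0.37, max_lag_s = 5,
                                  exclude_short = TRUE, mu = 1e-4, M = 1) {
  stopifnot(inherits(od, "od_series"))
  chans <- if (exclude_short) long_channels(od$layout)
           else seq_len(n_channels(od$layout))
  out <- od$od
  diag <- expand.grid(channel = chans, wavelength = od$layout$wavelengths)
  diag$n_accepted <- 0L
  diag$removed_fraction <- 0
  diag$flag <- ""
  pairs <- list()
  for (w in 1:2) {
    X <- od$od[, chans, w, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, ncol = 1)
    for (i in seq_along(chans)) {
      x <- X[, i]
      drow <- diag$channel == chans[i] & diag$wavelength == od$layout$wavelengths[w]
      if (length(chans) < 2 || stats::sd(x) == 0) {
        diag$flag[drow] <- "no correlated channels"
        next
      }
      aligned <- matrix(NA_real_, nrow(X), 0)
      for (j in seq_along(chans)) {
        if (j == i) next
        cc <- crosscorr_optimal_lag(x, X[, j], od$fs, max_lag_s)
        pairs[[length(pairs) + 1]] <- data.frame(
          wavelength = od$layout$wavelengths[w],
          target = chans[i], partner = chans[j],
          lag_s = cc$lag_s, r = cc$r)
        if (cc$r > r_thresh && abs(cc$lag_s) <= max_lag_s) {
          aligned <- cbind(aligned, align_by_lag(X[, j], cc$lag_samples))
        }
      }
      if (ncol(aligned) == 0) {
        diag$flag[drow] <- "no correlated channels"
        next
      }
      global <- rowMeans(aligned, na.rm = TRUE)
      global[!is.finite(global)] <- 0
      af <- adaptive_filter_regress(x, global, mu, M)
      out[, chans[i], w] <- af$residual
      diag$n_accepted[drow] <- ncol(aligned)
      diag$removed_fraction[drow] <- af$removed_fraction
    }
  }
  list(od = od_series(out, od$fs, od$layout), diagnostics = diag,
       pairs = do.call(rbind, pairs))
}

#' Empirical null for the lag-optimized correlation threshold
#'
#' Simulates pairs of independent (optionally band-limited) Gaussian series
#' of the study's length, takes each pair's maximum lag-optimized
#' correlation within the lag window, and returns the requested quantile —
#' an empirical acceptance threshold for [lagged_global_average()], which
#' users can recompute for their own series length and band.
#'
#' @param n_samples series length
#' @param fs sampling rate (Hz)
#' @param band band limits in Hz, or `NULL` for white noise
#' @param n_sims number of simulated pairs (values below 100 are flagged)
#' @param quantile_p null quantile to return (default 0.95)
#' @param max_lag_s lag window (0 for zero-lag correlation only)
#' @param seed RNG seed
#' @return numeric threshold, with attribute `"flag"` if `n_sims < 100`
#' @export
correlation_threshold_simulation <- function(n_samples, fs, band = NULL,
                                             n_sims = 500, quantile_p = 0.95,
                                             max_lag_s = 5, seed = 1) {
  set.seed(seed)
  flag <- NULL
  if (n_sims < 100) flag <- "n_sims < 100: threshold estimate is unstable"
  vals <- replicate(n_sims, {
    mk <- function() {
      if (is.null(band)) stats::rnorm(n_samples)
      else bandlimited_noise(n_samples, fs, band)
    }
    x <- mk(); y <- mk()
    if (max_lag_s <= 0) stats::cor(x, y)
    else crosscorr_optimal_lag(x, y, fs, max_lag_s)$r
  })
  out <- stats::quantile(vals, quantile_p, names = FALSE, type = 1)
  if (!is.null(flag)) attr(out, "flag") <- flag
  out
}

#' Apply an LF de-noising method by name
#'
#' Dispatches to the three strategies, respecting each method's operating
#' space: PCA and the delay-corrected global average run on (filtered)
#' optical density and conversion to concentration happens downstream;
#' short-separation regression runs on concentrations.
#'
#' @param od a band-passed [od_series()]
#' @param method `"none"`, `"ssd"`, `"pca"`, or `"gloavg"`
#' @param age_years subject age for the OD-to-concentration conversion
#' @param ... method parameters
#' @return list with `conc` (final [conc_series()]) and `diagnostics`
#' @export
denoise <- function(od, method = c("none", "ssd", "pca", "gloavg"),
                    age_years, ...) {
  method <- match.arg(method)
  switch(method,
    none = list(conc = od_to_concentration(od, age_years), diagnostics = NULL),
    ssd = {
      conc <- od_to_concentration(od, age_years)
      res <- ssd_denoise(conc, ...)
      list(conc = res$conc, diagnostics = res$diagnostics)
    },
    pca = {
      res <- pca_denoise(od, ...)
      list(conc = od_to_concentration(res$od, age_years),
           diagnostics = res$diagnostics)
    },
    gloavg = {
      res <- lagged_global_average(od, ...)
      list(conc = od_to_concentration(res$od, age_years),
           diagnostics = res$diagnostics)
    })
}
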