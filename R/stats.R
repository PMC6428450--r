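# Block metrics, the prewhitened robust GLM with HRF derivatives,
# Benjamini-Hochberg adjustment, activation rules and method-comparison
# statistics.

#' Block-average pre/task window means
#'
#' For every block: the rest baseline ("pre") is the mean over
#' `[onset - 4, onset)` s and the task response ("dur") the mean over
#' `[onset + 5, onset + 15)` s (a 5 s hemodynamic delay plus the 10 s task).
#' Blocks whose windows fall outside the recording are dropped (with their
#' count recorded).
#'
#' @param x numeric series
#' @param fs sampling rate (Hz)
#' @param onsets block onsets (s)
#' @param pre_window,dur_window window bounds relative to onset (s)
#' @return list with `pre`, `dur` (per-block means), `blocks` (kept block
#'   indices) and `n_dropped`
#' @export
block_average <- function(x, fs, onsets, pre_window = c(-4, 0),
                          dur_window = c(5, 15)) {
  bw <- block_windows_mean(x, fs, onsets, pre_window, dur_window)
  if (length(bw$pre) == 0) {
    stop("block_average: no usable blocks (all windows outside recording)")
  }
  bw$n_dropped <- length(onsets) - length(bw$blocks)
  bw
}

#' Cohen's d of a block design
#'
#' `(mean(dur) - mean(pre)) / sd(pre)` over the per-block window means,
#' with the sample standard deviation.
#'
#' @param pre_samples,dur_samples per-block pre/task means
#' @return signed effect size
#' @export
cohens_d <- function(pre_samples, dur_samples) {
  if (length(pre_samples) < 2) stop("cohens_d: need >= 2 pre samples")
  s <- stats::sd(pre_samples)
  if (s == 0) stop("cohens_d: undefined (zero pre-window variance)")
  (mean(dur_samples) - mean(pre_samples)) / s
}

#' Contrast-to-noise ratio of a block design
#'
#' `|mean(dur) - mean(pre)| / sqrt(var(dur) + var(pre))` over the per-block
#' window means.
#'
#' @param pre_samples,dur_samples per-block pre/task means
#' @return nonnegative CNR
#' @export
cnr <- function(pre_samples, dur_samples) {
  v <- stats::var(dur_samples) + stats::var(pre_samples)
  if (!is.finite(v) || v == 0) stop("cnr: undefined (zero combined variance)")
  abs(mean(dur_samples) - mean(pre_samples)) / sqrt(v)
}

#' Per-channel block metrics for both hemoglobin species
#'
#' @param conc a [conc_series()]
#' @param design a [stimulus_design()]
#' @param ... window arguments passed to [block_average()]
#' @return data.frame: channel, species, mean_pre, mean_dur, cohens_d, cnr
#' @export
block_metrics <- function(conc, design, ...) {
  stopifnot(inherits(conc, "conc_series"))
  nc <- ncol(conc$hbo)
  rows <- list()
  for (sp in c("hbo", "hbr")) {
    mat <- conc[[sp]]
    for (ch in seq_len(nc)) {
      ba <- block_average(mat[, ch], conc$fs, design$onsets, ...)
      rows[[length(rows) + 1]] <- data.frame(
        channel = ch, species = sp,
        mean_pre = mean(ba$pre), mean_dur = mean(ba$dur),
        cohens_d = cohens_d(ba$pre, ba$dur),
        cnr = cnr(ba$pre, ba$dur))
    }
  }
  do.call(rbind, rows)
}

#' Maximum metric over the region of interest
#'
#' The per-subject ROI summary: the signed maximum for oxyhemoglobin
#' effect sizes, the most negative value for deoxyhemoglobin effect sizes
#' (whose task response is a decrease), or the absolute maximum for CNR.
#'
#' @param values per-channel metric values
#' @param roi ROI channel indices (non-empty, in range)
#' @param mode `"signed_max"`, `"most_negative"` or `"abs_max"`
#' @return scalar summary
#' @export
roi_max_metric <- function(values, roi,
                           mode = c("signed_max", "most_negative", "abs_max")) {
  mode <- match.arg(mode)
  if (length(roi) == 0) stop("roi_max_metric: empty ROI")
  if (any(roi < 1 | roi > length(values))) stop("roi_max_metric: ROI index out of range")
  v <- values[roi]
  switch(mode,
         signed_max = max(v),
         most_negative = v[which.min(v)],
         abs_max = v[which.max(abs(v))])
}

#' GLM design matrix with canonical HRF and temporal derivatives
#'
#' Columns: intercept; the block boxcar convolved with the canonical HRF
#' (main task regressor); optionally its first temporal derivative and a
#' second-derivative curvature (dispersion-like) term. Derivative columns
#' are orthogonalized against the preceding columns so the main-term
#' estimate keeps its interpretation.
#'
#' @param stimulus a [stimulus_design()]
#' @param fs sampling rate (Hz)
#' @param n_samples series length; must cover at least one block
#' @param include_derivatives add the two derivative columns (default TRUE)
#' @param hrf HRF kernel (default [canonical_hrf()] at `fs`)
#' @return numeric matrix with named columns
#' @export
build_design_matrix <- function(stimulus, fs, n_samples,
                                include_derivatives = TRUE,
                                hrf = canonical_hrf(fs)) {
  if (n_samples < (stimulus$task_duration + stimulus$rest_duration) * fs) {
    stop("build_design_matrix: series shorter than one block")
  }
  main <- task_regressor(stimulus, fs, n_samples, hrf = hrf)
  X <- cbind(intercept = 1, main = main)
  if (include_derivatives) {
    d1 <- c(0, diff(main)) * fs
    d2 <- c(0, diff(d1)) * fs
    orth <- function(v, basis) {
      stats::lm.fit(basis, v)$residuals
    }
    d1o <- orth(d1, X)
    d2o <- orth(d2, cbind(X, d1o))
    X <- cbind(X, deriv1 = d1o, deriv2 = d2o)
  }
  X
}

#' Prewhiten a regression system with an autoregressive error model
#'
#' Fits AR(p) to the OLS residuals (order chosen by BIC up to
#' `max_ar_order`), then filters both response and design with the AR
#' whitening operator `e_t = y_t - sum(phi_i y_(t-i))`, dropping the first
#' `p` rows. Low-pass filtered hemodynamic series are strongly
#' autocorrelated; without this step GLM t-statistics are inflated.
#'
#' @param y response series
#' @param X design matrix
#' @param max_ar_order maximum AR order (default `ceiling(4 * fs)` via the
#'   caller; here a plain integer)
#' @return list with `y_w`, `X_w`, `ar_coefficients`, `order`, and
#'   `fallback` (TRUE when a non-stationary fit forced the AR(1) fallback)
#' @export
prewhiten <- function(y, X, max_ar_order = 16) {
  n <- length(y)
  if (n <= max_ar_order * 3) stop("prewhiten: series too short for AR estimation")
  res <- stats::lm.fit(X, y)$residuals
  pick <- select_ar_bic(res, max_ar_order)
  phi <- pick$phi
  fallback <- FALSE
  if (length(phi) && any(Mod(polyroot(c(1, -phi))) <= 1)) {
    # non-stationary fit; fall back to AR(1)
    phi <- stats::acf(res, lag.max = 1, plot = FALSE)$acf[2]
    phi <- max(min(phi, 0.99), -0.99)
    fallback <- TRUE
  }
  p <- length(phi)
  if (p == 0) {
    return(list(y_w = y, X_w = X, ar_coefficients = numeric(0), order = 0L,
                fallback = FALSE))
  }
  whiten <- function(v) {
    out <- v[(p + 1):n]
    for (i in seq_len(p)) out <- out - phi[i] * v[(p + 1 - i):(n - i)]
    out
  }
  list(y_w = whiten(y),
       X_w = apply(X, 2, whiten),
       ar_coefficients = phi, order = p, fallback = fallback)
}

# BIC-based AR order selection on a residual series (Burg estimates)
select_ar_bic <- function(res, max_order) {
  n <- length(res)
  best <- list(bic = Inf, phi = numeric(0))
  v0 <- stats::var(res)
  bic0 <- n * log(v0)
  if (bic0 < best$bic) best <- list(bic = bic0, phi = numeric(0))
  for (p in seq_len(max_order)) {
    fit <- try(stats::ar(res, aic = FALSE, order.max = p, method = "burg"),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    bic <- n * log(fit$var.pred) + p * log(n)
    if (is.finite(bic) && bic < best$bic) {
      best <- list(bic = bic, phi = as.numeric(fit$ar))
    }
  }
  best
}

#' Prewhitened robust GLM for one channel series
#'
#' Optionally prewhitens the system ([prewhiten()]), then fits by
#' iteratively reweighted least squares with the Tukey bisquare weight
#' function (tuning constant 4.685). Inference is reported for the main
#' task column only: its t statistic and two-sided p value.
#'
#' @param y response series (one channel, one species)
#' @param X design matrix from [build_design_matrix()] (full column rank)
#' @param prewhiten_errors apply the AR prewhitening step (default TRUE)
#' @param max_ar_order maximum AR order for prewhitening
#' @param main_col name of the inference column (default `"main"`)
#' @return list: `beta_main`, `t_main`, `p`, `beta` (all coefficients),
#'   `ar_order`, `df_residual`, `converged`
#' @export
robust_glm <- function(y, X, prewhiten_errors = TRUE, max_ar_order = 16,
                       main_col = "main") {
  if (qr(X)$rank < ncol(X)) stop("robust_glm: design matrix is rank deficient")
  ar_order <- 0L
  if (prewhiten_errors) {
    pw <- prewhiten(y, X, max_ar_order)
    y <- pw$y_w; X <- pw$X_w; ar_order <- pw$order
  }
  fit <- MASS::rlm(X, y, psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  sm <- summary(fit)
  j <- match(main_col, colnames(X))
  tval <- sm$coefficients[j, "t value"]
  df <- length(y) - ncol(X)
  list(beta_main = unname(stats::coef(fit)[j]),
       t_main = unname(tval),
       p = 2 * stats::pt(-abs(tval), df = df),
       beta = stats::coef(fit),
       ar_order = ar_order,
       df_residual = df,
       converged = fit$converged)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted q values (monotone).
#'
#' @param p_values numeric in `[0, 1]`
#' @return q values, same length
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("bh_adjust: p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Channel-wise GLM for both hemoglobin species
#'
#' Runs [robust_glm()] per channel and species on de-noised concentration
#' changes and BH-adjusts p values across the included channels, per
#' species.
#'
#' @param conc a [conc_series()]
#' @param design a [stimulus_design()]
#' @param channels channels to analyze (default: long channels); excluded
#'   channels appear in the output with `NA` statistics
#' @param include_derivatives,prewhiten_errors,max_ar_order see
#'   [build_design_matrix()] and [robust_glm()]
#' @return data.frame: channel, species, beta_main, t, p, q, ar_order,
#'   included
#' @export
glm_activation <- function(conc, design, channels = NULL,
                           include_derivatives = TRUE,
                           prewhiten_errors = TRUE,
                           max_ar_order = NULL) {
  stopifnot(inherits(conc, "conc_series"))
  nc <- ncol(conc$hbo)
  if (is.null(channels)) channels <- long_channels(conc$layout)
  if (is.null(max_ar_order)) max_ar_order <- ceiling(4 * conc$fs)
  X <- build_design_matrix(design, conc$fs, nrow(conc$hbo),
                           include_derivatives)
  rows <- list()
  for (sp in c("hbo", "hbr")) {
    mat <- conc[[sp]]
    stats_list <- lapply(channels, function(ch) {
      robust_glm(mat[, ch], X, prewhiten_errors, max_ar_order)
    })
    p <- vapply(stats_list, `[[`, numeric(1), "p")
    q <- bh_adjust(p)
    for (i in seq_along(channels)) {
      rows[[length(rows) + 1]] <- data.frame(
        channel = channels[i], species = sp,
        beta_main = stats_list[[i]]$beta_main,
        t = stats_list[[i]]$t_main,
        p = p[i], q = q[i],
        ar_order = stats_list[[i]]$ar_order,
        included = TRUE)
    }
    for (ch in setdiff(seq_len(nc), channels)) {
      rows[[length(rows) + 1]] <- data.frame(
        channel = ch, species = sp, beta_main = NA_real_, t = NA_real_,
        p = NA_real_, q = NA_real_, ar_order = NA_integer_,
        included = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$species, out$channel), ]
}

#' Activation decision under the three criteria
#'
#' A channel is oxy-active when its HbO q value is below `alpha` with a
#' positive task beta; deoxy-active when its HbR q value is below `alpha`
#' with a negative beta; combined-active only when both hold — the
#' physiologically grounded criterion (neurovascular coupling raises HbO
#' while lowering HbR).
#'
#' @param glm_result output of [glm_activation()] (both species)
#' @param alpha significance level on q (default 0.05)
#' @return data.frame: channel, oxy_active, deoxy_active, combined_active,
#'   alpha
#' @export
activation_decision <- function(glm_result, alpha = 0.05) {
  hbo <- glm_result[glm_result$species == "hbo", ]
  hbr <- glm_result[glm_result$species == "hbr", ]
  hbr <- hbr[match(hbo$channel, hbr$channel), ]
  oxy <- !is.na(hbo$q) & hbo$q < alpha & hbo$beta_main > 0
  deoxy <- !is.na(hbr$q) & hbr$q < alpha & hbr$beta_main < 0
  data.frame(channel = hbo$channel,
             oxy_active = oxy, deoxy_active = deoxy,
             combined_active = oxy & deoxy,
             alpha = alpha)
}

#' Paired t tests with Benjamini-Hochberg correction across comparisons
#'
#' @param pairs named list; each element a list/data.frame with components
#'   `a` and `b` (paired vectors, n >= 3)
#' @return data.frame: comparison, t, df, p, p_c (BH-adjusted)
#' @export
paired_t_bh <- function(pairs) {
  rows <- lapply(names(pairs), function(nm) {
    a <- pairs[[nm]]$a; b <- pairs[[nm]]$b
    if (length(a) != length(b)) {
      stop("paired_t_bh: lengths differ in comparison ", nm)
    }
    if (length(a) < 3) stop("paired_t_bh: need n >= 3 pairs in ", nm)
    d <- a - b
    if (stats::sd(d) <= 1e-12 * (abs(mean(d)) + 1)) {
      # constant difference: the t statistic degenerates
      data.frame(comparison = nm, t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                 df = length(d) - 1, p = if (mean(d) == 0) 1 else 0)
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      data.frame(comparison = nm, t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_c <- bh_adjust(out$p)
  out
}

#' Pearson correlation between two method time courses
#'
#' @param series_a,series_b equal-length series with nonzero variance
#' @return correlation coefficient
#' @export
method_correlation <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) {
    stop("method_correlation: lengths differ")
  }
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0) {
    stop("method_correlation: undefined for zero-variance series")
  }
  stats::cor(series_a, series_b)
}
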