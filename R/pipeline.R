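# End-to-end orchestration: single-recording processing, factorial method
# comparison over simulated cohorts, and report rendering.

registered_methods <- list(
  exclude = c("none", "cv", "phoebe"),
  mc = c("none", "iqr_wavelet", "kurtosis_wavelet"),
  filter = c("none", "bw_seq", "bw_direct", "fft"),
  denoise = c("none", "ssd", "pca", "gloavg")
)

check_method <- function(value, what) {
  ok <- registered_methods[[what]]
  if (!value %in% ok) {
    stop("unknown ", what, " method '", value, "'; registered: ",
         paste(ok, collapse = ", "))
  }
  value
}

#' Process one recording through the full pipeline
#'
#' Stage order: channel exclusion on the raw recording; intensity to
#' optical density; wavelet motion correction; zero-phase band-pass;
#' low-frequency de-noising (PCA and the delay-corrected global average on
#' OD with conversion to concentration afterwards, short-separation
#' regression on concentrations); prewhitened robust GLM with the
#' combined-criterion activation decision. Excluded channels are carried
#' through as `NA` rows in the GLM table, never dropped.
#'
#' @param rec a [raw_recording()]
#' @param exclude_method `"none"`, `"cv"` or `"phoebe"`
#' @param mc_method `"none"`, `"iqr_wavelet"` (MC#1) or
#'   `"kurtosis_wavelet"` (MC#2)
#' @param filter_method `"none"`, `"bw_seq"`, `"bw_direct"` or `"fft"`
#' @param denoise_method `"none"`, `"ssd"`, `"pca"` or `"gloavg"`
#' @param include_derivatives GLM derivative columns (default TRUE)
#' @param prewhiten_errors GLM prewhitening (default TRUE)
#' @param alpha significance level on q (default 0.05)
#' @param band band-pass edges in Hz
#' @return list: `quality`, `conc`, `metrics` (block metrics), `glm`,
#'   `decisions`, `excluded`, `stages` (method names used)
#' @export
process_recording <- function(rec,
                              exclude_method = "phoebe",
                              mc_method = "iqr_wavelet",
                              filter_method = "bw_seq",
                              denoise_method = "gloavg",
                              include_derivatives = TRUE,
                              prewhiten_errors = TRUE,
                              alpha = 0.05,
                              band = c(0.01, 0.2)) {
  check_method(exclude_method, "exclude")
  check_method(mc_method, "mc")
  check_method(filter_method, "filter")
  check_method(denoise_method, "denoise")

  quality <- switch(exclude_method,
                    none = NULL,
                    cv = cv_exclusion(rec),
                    phoebe = phoebe_exclusion(rec))
  excluded <- if (is.null(quality)) integer() else excluded_channels(quality)

  od <- intensity_to_od(rec)
  od <- motion_correct(od, mc_method)
  od <- filter_od(od, filter_method, lo = band[1], hi = band[2])
  den <- denoise(od, denoise_method, age_years = rec$subject_age)

  channels <- setdiff(long_channels(rec$layout), excluded)
  glm <- glm_activation(den$conc, rec$stimulus, channels = channels,
                        include_derivatives = include_derivatives,
                        prewhiten_errors = prewhiten_errors)
  decisions <- activation_decision(glm, alpha = alpha)
  metrics <- block_metrics(den$conc, rec$stimulus)
  list(quality = quality, conc = den$conc, metrics = metrics, glm = glm,
       decisions = decisions, excluded = excluded,
       denoise_diagnostics = den$diagnostics,
       stages = c(exclude = exclude_method, mc = mc_method,
                  filter = filter_method, denoise = denoise_method,
                  derivatives = include_derivatives,
                  prewhiten = prewhiten_errors))
}

#' Pipeline configuration for a factorial cohort run
#'
#' Each stage selection may be a vector; [run_pipeline()] expands the full
#' factorial of selections and runs every combination on every simulated
#' subject. Stages upstream of the de-noiser are computed once per subject
#' per upstream setting, so changing only the de-noiser cannot perturb
#' earlier stages.
#'
#' @param exclude_method,mc_method,filter_method,denoise_method stage
#'   selections (vectors allowed)
#' @param include_derivatives logical vector of GLM variants
#' @param n_subjects simulated cohort size
#' @param base_seed subject `i` uses seed `base_seed + i - 1`
#' @param sim a [sim_config()]
#' @param alpha significance level
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(exclude_method = "phoebe",
                            mc_method = "iqr_wavelet",
                            filter_method = "bw_seq",
                            denoise_method = "gloavg",
                            include_derivatives = TRUE,
                            n_subjects = 4, base_seed = 1,
                            sim = sim_config(), alpha = 0.05) {
  for (m in exclude_method) check_method(m, "exclude")
  for (m in mc_method) check_method(m, "mc")
  for (m in filter_method) check_method(m, "filter")
  for (m in denoise_method) check_method(m, "denoise")
  structure(list(exclude_method = exclude_method, mc_method = mc_method,
                 filter_method = filter_method,
                 denoise_method = denoise_method,
                 include_derivatives = include_derivatives,
                 n_subjects = n_subjects, base_seed = base_seed,
                 sim = sim, alpha = alpha),
            class = "pipeline_config")
}

#' Run the factorial pipeline on a simulated cohort
#'
#' @param config a [pipeline_config()]
#' @return list of class `result_bundle`: `combos` (data.frame of method
#'   combinations), `subjects` (per subject: seed, ground truth, and one
#'   result per combination from [process_recording()]), `config`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  combos <- expand.grid(exclude = config$exclude_method,
                        mc = config$mc_method,
                        filter = config$filter_method,
                        denoise = config$denoise_method,
                        derivatives = config$include_derivatives,
                        stringsAsFactors = FALSE)
  combos$label <- apply(combos, 1, function(r) {
    paste0(r[["denoise"]], if (as.logical(r[["derivatives"]])) "+deriv" else "-deriv",
           "/", r[["exclude"]], "/", r[["mc"]], "/", r[["filter"]])
  })
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    seed <- config$base_seed + i - 1
    sim <- simulate_recording(config$sim, seed = seed)
    results <- vector("list", nrow(combos))
    for (k in seq_len(nrow(combos))) {
      results[[k]] <- process_recording(
        sim$recording,
        exclude_method = combos$exclude[k],
        mc_method = combos$mc[k],
        filter_method = combos$filter[k],
        denoise_method = combos$denoise[k],
        include_derivatives = combos$derivatives[k],
        alpha = config$alpha)
    }
    subjects[[i]] <- list(seed = seed, truth = sim$truth, results = results)
  }
  structure(list(combos = combos, subjects = subjects, config = config),
            class = "result_bundle")
}

# fraction (in %) of subjects whose ROI contains >= 1 active channel
roi_detection_pct <- function(bundle, k, criterion) {
  roi <- default_roi(bundle)
  mean(vapply(bundle$subjects, function(s) {
    dec <- s$results[[k]]$decisions
    any(dec[[criterion]][dec$channel %in% roi])
  }, logical(1))) * 100
}

default_roi <- function(bundle) {
  # ROI is a property of the simulated layout (identical across subjects)
  lay <- default_layout(bundle$config$sim$n_long, bundle$config$sim$n_short)
  lay$roi_channels
}

#' Summaries and pairwise comparisons across method combinations
#'
#' Produces the group-level summaries used to compare processing choices:
#' percentage of subjects with ROI activation per criterion; mean
#' percentage of significant channels outside the ROI; the most often
#' activated ROI channel; ROI-maximum effect-size summaries; pairwise
#' cleaned-time-course correlations between combinations; and paired
#' t tests (BH-corrected) of outside-ROI rates between combinations.
#'
#' @param bundle a `result_bundle` from [run_pipeline()]
#' @return list of class `comparison_report`
#' @export
compare_methods <- function(bundle) {
  stopifnot(inherits(bundle, "result_bundle"))
  combos <- bundle$combos
  nk <- nrow(combos)
  roi <- default_roi(bundle)
  crit <- c("oxy_active", "deoxy_active", "combined_active")

  detection <- expand.grid(combo = combos$label, criterion = crit,
                           stringsAsFactors = FALSE)
  detection$pct_subjects <- NA_real_
  outside <- detection
  outside$mean_pct_channels <- NA_real_
  outside$mean_pct_channels <- NULL
  outside$pct_subjects <- NULL
  outside$mean_pct_channels <- NA_real_

  roi_channel_pct <- list()
  roi_metrics <- list()
  per_subject_outside <- array(NA_real_, c(length(bundle$subjects), nk,
                                           length(crit)))

  for (k in seq_len(nk)) {
    for (ci in seq_along(crit)) {
      cn <- crit[ci]
      detection$pct_subjects[detection$combo == combos$label[k] &
                               detection$criterion == cn] <-
        roi_detection_pct(bundle, k, cn)
      out_rates <- vapply(bundle$subjects, function(s) {
        dec <- s$results[[k]]$decisions
        keep <- !dec$channel %in% roi
        100 * mean(dec[[cn]][keep])
      }, numeric(1))
      per_subject_outside[, k, ci] <- out_rates
      outside$mean_pct_channels[outside$combo == combos$label[k] &
                                  outside$criterion == cn] <- mean(out_rates)
    }
    # per-ROI-channel activation percentage (combined criterion)
    pct <- vapply(roi, function(ch) {
      100 * mean(vapply(bundle$subjects, function(s) {
        dec <- s$results[[k]]$decisions
        isTRUE(dec$combined_active[dec$channel == ch])
      }, logical(1)))
    }, numeric(1))
    roi_channel_pct[[k]] <- data.frame(combo = combos$label[k], channel = roi,
                                       pct_subjects = pct)
    # ROI max Cohen's d / CNR per subject
    roi_metrics[[k]] <- do.call(rbind, lapply(seq_along(bundle$subjects),
      function(i) {
        m <- bundle$subjects[[i]]$results[[k]]$metrics
        hbo_d <- m$cohens_d[m$species == "hbo"]
        hbr_d <- m$cohens_d[m$species == "hbr"]
        hbo_c <- m$cnr[m$species == "hbo"]
        data.frame(combo = combos$label[k], subject = i,
                   max_d_hbo = roi_max_metric(hbo_d, roi, "signed_max"),
                   max_d_hbr = roi_max_metric(hbr_d, roi, "most_negative"),
                   max_cnr_hbo = roi_max_metric(hbo_c, roi, "abs_max"))
      }))
  }
  roi_channel_pct <- do.call(rbind, roi_channel_pct)
  roi_metrics <- do.call(rbind, roi_metrics)
  most_activated <- do.call(rbind, lapply(split(roi_channel_pct,
                                                roi_channel_pct$combo),
    function(d) d[which.max(d$pct_subjects), ]))

  pairwise <- NULL
  paired_tests <- NULL
  note <- NULL
  if (nk >= 2) {
    pairs_idx <- utils::combn(nk, 2)
    rows <- list()
    tests <- list()
    for (j in seq_len(ncol(pairs_idx))) {
      k1 <- pairs_idx[1, j]; k2 <- pairs_idx[2, j]
      cors <- unlist(lapply(bundle$subjects, function(s) {
        c1 <- s$results[[k1]]$conc; c2 <- s$results[[k2]]$conc
        vapply(roi, function(ch)
          method_correlation(c1$hbo[, ch], c2$hbo[, ch]), numeric(1))
      }))
      rows[[j]] <- data.frame(combo_a = combos$label[k1],
                              combo_b = combos$label[k2],
                              mean_r_hbo = mean(cors))
      nm <- paste(combos$label[k1], "vs", combos$label[k2])
      tests[[nm]] <- list(a = per_subject_outside[, k1, 3],
                          b = per_subject_outside[, k2, 3])
    }
    pairwise <- do.call(rbind, rows)
    if (length(bundle$subjects) >= 3) paired_tests <- paired_t_bh(tests)
  } else {
    note <- "single method combination: pairwise comparisons skipped"
  }
  structure(list(detection = detection, outside_roi = outside,
                 roi_channel_pct = roi_channel_pct,
                 most_activated = most_activated,
                 roi_metrics = roi_metrics,
                 pairwise_correlation = pairwise,
                 paired_tests = paired_tests,
                 note = note),
            class = "comparison_report")
}

#' Write a comparison report to disk
#'
#' CSV tables, a machine-readable JSON summary, and (when ggplot2 is
#' available) PNG figures: a pairwise-correlation heatmap and a
#' per-channel activation map.
#'
#' @param report a `comparison_report` from [compare_methods()]
#' @param outdir output directory (created if needed)
#' @return character vector of files written
#' @export
render_report <- function(report, outdir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    if (is.null(df)) return()
    f <- file.path(outdir, paste0(name, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  wr(report$detection, "roi_detection")
  wr(report$outside_roi, "outside_roi_rates")
  wr(report$roi_channel_pct, "roi_channel_pct")
  wr(report$most_activated, "most_activated_channel")
  wr(report$roi_metrics, "roi_metrics")
  wr(report$pairwise_correlation, "pairwise_correlation")
  wr(report$paired_tests, "paired_tests")
  jf <- file.path(outdir, "summary.json")
  jsonlite::write_json(
    list(detection = report$detection,
         outside_roi = report$outside_roi,
         most_activated = report$most_activated,
         note = report$note),
    jf, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  files <- c(files, jf)
  if (requireNamespace("ggplot2", quietly = TRUE) &&
      !is.null(report$pairwise_correlation)) {
    g <- ggplot2::ggplot(report$pairwise_correlation,
                         ggplot2::aes(x = combo_a, y = combo_b,
                                      fill = mean_r_hbo)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
      ggplot2::labs(x = NULL, y = NULL, fill = "r") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
    pf <- file.path(outdir, "pairwise_correlation.png")
    ggplot2::ggsave(pf, g, width = 7, height = 5, dpi = 120)
    files <- c(files, pf)
  }
  files
}
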