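#' @keywords internal
"_PACKAGE"

# ---- core domain types -------------------------------------------------
#
# All time-indexed arrays are [time, channel] or [time, channel, wavelength],
# wavelengths sorted ascending. Time is seconds, 0-based from the first
# sample; stimulus onsets are seconds on the same axis.

#' Probe layout
#'
#' Describes the source-detector channel geometry of an fNIRS montage: one row
#' per channel with optode ids, inter-optode distance and a short-channel flag,
#' plus the two measurement wavelengths and the set of region-of-interest
#' (ROI) channels used for activation summaries.
#'
#' @param channels data.frame with columns `source_id`, `detector_id`,
#'   `distance_mm` (> 0) and `is_short` (logical). Short channels sample
#'   mostly extracerebral tissue and serve as systemic references.
#' @param wavelengths numeric vector of exactly two distinct wavelengths in
#'   nm; stored sorted ascending.
#' @param roi_channels integer indices (into `channels` rows) of the
#'   region-of-interest channels.
#' @param short_max_mm upper bound (mm) a channel flagged short may have.
#' @return An object of class `probe_layout`.
#' @export
probe_layout <- function(channels, wavelengths = c(760, 850),
                         roi_channels = integer(), short_max_mm = 20) {
  stopifnot(is.data.frame(channels))
  req <- c("source_id", "detector_id", "distance_mm", "is_short")
  missing_cols <- setdiff(req, names(channels))
  if (length(missing_cols)) {
    stop("probe_layout: channels is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(wavelengths) != 2 || anyDuplicated(wavelengths)) {
    stop("probe_layout: exactly two distinct wavelengths are required")
  }
  if (any(channels$distance_mm <= 0)) {
    stop("probe_layout: channel distances must be positive")
  }
  if (any(channels$is_short & channels$distance_mm > short_max_mm)) {
    stop("probe_layout: short channels must be <= ", short_max_mm, " mm")
  }
  if (!any(!channels$is_short)) {
    stop("probe_layout: at least one non-short channel is required")
  }
  roi_channels <- as.integer(roi_channels)
  if (length(roi_channels) &&
      (any(roi_channels < 1) || any(roi_channels > nrow(channels)))) {
    stop("probe_layout: roi_channels out of range")
  }
  structure(
    list(channels = channels,
         wavelengths = sort(as.numeric(wavelengths)),
         roi_channels = roi_channels,
         short_max_mm = short_max_mm),
    class = "probe_layout"
  )
}

#' Number of channels in a layout
#' @param layout a [probe_layout()]
#' @return integer count
#' @export
n_channels <- function(layout) nrow(layout$channels)

#' Indices of long (non-short) channels
#' @param layout a [probe_layout()]
#' @return integer vector
#' @export
long_channels <- function(layout) which(!layout$channels$is_short)

#' Indices of short channels
#' @param layout a [probe_layout()]
#' @return integer vector
#' @export
short_channels <- function(layout) which(layout$channels$is_short)

#' Block stimulus design
#'
#' A block paradigm: task blocks of fixed duration separated by fixed rest.
#' The fundamental task frequency is `1 / (task_duration + rest_duration)`.
#'
#' @param onsets numeric, strictly increasing block onsets in seconds.
#' @param task_duration seconds of task per block.
#' @param rest_duration seconds of rest between blocks.
#' @return An object of class `stimulus_design`.
#' @export
stimulus_design <- function(onsets, task_duration = 10, rest_duration = 15) {
  onsets <- as.numeric(onsets)
  if (length(onsets) == 0) stop("stimulus_design: at least one onset required")
  if (any(diff(onsets) <= 0)) {
    stop("stimulus_design: onsets must be strictly increasing")
  }
  if (task_duration <= 0 || rest_duration < 0) {
    stop("stimulus_design: durations must be positive")
  }
  structure(
    list(onsets = onsets, task_duration = task_duration,
         rest_duration = rest_duration, n_blocks = length(onsets)),
    class = "stimulus_design"
  )
}

#' Fundamental frequency and first harmonic of a block design
#'
#' The block paradigm concentrates task-evoked power at
#' `1/(task_duration + rest_duration)` and its harmonics; for a 10 s-on /
#' 15 s-off design this is 0.04 Hz with a first harmonic at 0.08 Hz.
#'
#' @param design a [stimulus_design()]
#' @return named numeric vector `c(fundamental =, first_harmonic =)` in Hz
#' @export
task_frequencies <- function(design) {
  f0 <- 1 / (design$task_duration + design$rest_duration)
  c(fundamental = f0, first_harmonic = 2 * f0)
}

#' Raw dual-wavelength fNIRS recording
#'
#' The pipeline entry point: strictly positive optical intensities indexed
#' `[time, channel, wavelength]`, plus sampling rate, probe geometry, block
#' design and subject age (used for the age-dependent differential path
#' length factor).
#'
#' @param intensity numeric array `[time, channel, wavelength]`, all > 0.
#' @param fs sampling rate in Hz (> 0).
#' @param layout a [probe_layout()]; `dim(intensity)[2]` must match.
#' @param stimulus a [stimulus_design()].
#' @param subject_age age in years (> 0).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(intensity, fs, layout, stimulus, subject_age) {
  stopifnot(inherits(layout, "probe_layout"),
            inherits(stimulus, "stimulus_design"))
  if (!is.array(intensity) || length(dim(intensity)) != 3) {
    stop("raw_recording: intensity must be a [time, channel, wavelength] array")
  }
  if (dim(intensity)[2] != n_channels(layout)) {
    stop("raw_recording: channel dimension (", dim(intensity)[2],
         ") does not match layout (", n_channels(layout), ")")
  }
  if (dim(intensity)[3] != 2) {
    stop("raw_recording: exactly two wavelength planes required")
  }
  if (fs <= 0) stop("raw_recording: fs must be positive")
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    stop("raw_recording: intensities must be finite and strictly positive")
  }
  if (subject_age <= 0) stop("raw_recording: subject_age must be positive")
  structure(
    list(intensity = intensity, fs = fs, layout = layout,
         stimulus = stimulus, subject_age = subject_age),
    class = "raw_recording"
  )
}

#' Optical density series
#'
#' Relative optical density `-log(I / mean(I))` per channel and wavelength;
#' the linear domain of the modified Beer-Lambert law.
#'
#' @param od numeric array `[time, channel, wavelength]` of finite values.
#' @param fs sampling rate in Hz.
#' @param layout a [probe_layout()].
#' @return An object of class `od_series`.
#' @export
od_series <- function(od, fs, layout) {
  stopifnot(inherits(layout, "probe_layout"))
  if (!is.array(od) || length(dim(od)) != 3) {
    stop("od_series: od must be a [time, channel, wavelength] array")
  }
  if (any(!is.finite(od))) stop("od_series: OD values must be finite")
  if (dim(od)[2] != n_channels(layout)) {
    stop("od_series: channel dimension does not match layout")
  }
  structure(list(od = od, fs = fs, layout = layout), class = "od_series")
}

#' Hemoglobin concentration-change series
#'
#' Oxy- (`hbo`) and deoxyhemoglobin (`hbr`) concentration changes in
#' micromolar, `[time, channel]`.
#'
#' @param hbo,hbr numeric matrices `[time, channel]`, same shape, finite.
#' @param fs sampling rate in Hz.
#' @param layout a [probe_layout()].
#' @return An object of class `conc_series`.
#' @export
conc_series <- function(hbo, hbr, fs, layout) {
  stopifnot(inherits(layout, "probe_layout"))
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  if (!identical(dim(hbo), dim(hbr))) {
    stop("conc_series: hbo and hbr must have identical shape")
  }
  if (any(!is.finite(hbo)) || any(!is.finite(hbr))) {
    stop("conc_series: concentrations must be finite")
  }
  structure(list(hbo = hbo, hbr = hbr, fs = fs, layout = layout),
            class = "conc_series")
}

#' Validate a raw recording without raising
#'
#' Checks every type invariant of a [raw_recording()] and reports violations
#' as a character vector of issue descriptions (empty when all hold). Unlike
#' the constructors this never raises, so it can triage malformed inputs.
#'
#' @param rec object to check (any shape; a well-formed `raw_recording`
#'   yields no issues)
#' @return character vector of issues, possibly empty
#' @export
validate_recording <- function(rec) {
  issues <- character()
  add <- function(msg) issues <<- c(issues, msg)
  if (!is.list(rec)) return("recording is not a list-like object")
  if (is.null(rec$fs) || !is.finite(rec$fs) || rec$fs <= 0) {
    add("non-positive sampling rate (fs)")
  }
  if (is.null(rec$intensity) || !is.array(rec$intensity) ||
      length(dim(rec$intensity)) != 3) {
    add("intensity is not a [time, channel, wavelength] array")
    return(issues)
  }
  d <- dim(rec$intensity)
  if (any(!is.finite(rec$intensity)) || any(rec$intensity <= 0)) {
    bad <- which(!is.finite(rec$intensity) | rec$intensity <= 0,
                 arr.ind = TRUE)
    add(sprintf("non-positive or non-finite intensity (first at t=%d, channel=%d, wavelength plane=%d)",
                bad[1, 1], bad[1, 2], bad[1, 3]))
  }
  if (!is.null(rec$layout)) {
    if (d[2] != n_channels(rec$layout)) {
      add("channel dimension does not match probe layout")
    }
    if (length(rec$layout$wavelengths) != 2) {
      add("layout does not declare exactly two wavelengths")
    }
  } else add("missing probe layout")
  if (!is.null(rec$stimulus) && !is.null(rec$fs) && rec$fs > 0) {
    dur <- d[1] / rec$fs
    ends <- rec$stimulus$onsets + rec$stimulus$task_duration
    if (any(ends > dur)) {
      add(sprintf("stimulus_design: %d onset(s) extend beyond recording end (%.1f s)",
                  sum(ends > dur), dur))
    }
    if (any(diff(rec$stimulus$onsets) <= 0)) {
      add("stimulus_design: onsets not strictly increasing")
    }
  } else if (is.null(rec$stimulus)) add("missing stimulus design")
  if (!is.null(rec$subject_age) && (!is.finite(rec$subject_age) ||
                                    rec$subject_age <= 0)) {
    add("non-positive subject age")
  }
  issues
}

#' @export
print.raw_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<raw_recording> %d samples x %d channels x 2 wavelengths (%g/%g nm)\n",
              d[1], d[2], x$layout$wavelengths[1], x$layout$wavelengths[2]))
  cat(sprintf("  fs = %g Hz (%.1f s), %d blocks of %g s on / %g s off, age %g y\n",
              x$fs, d[1] / x$fs, x$stimulus$n_blocks,
              x$stimulus$task_duration, x$stimulus$rest_duration,
              x$subject_age))
  invisible(x)
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout> %d channels (%d short), wavelengths %g/%g nm, ROI: %s\n",
              n_channels(x), sum(x$channels$is_short),
              x$wavelengths[1], x$wavelengths[2],
              if (length(x$roi_channels)) paste(x$roi_channels, collapse = ", ")
              else "none"))
  invisible(x)
}

# internal: seconds -> sample index (1-based), time 0 = first sample
time_to_index <- function(t_s, fs) as.integer(round(t_s * fs)) + 1L
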