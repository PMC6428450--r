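# Readers and writers: SNIRF (the canonical fNIRS container, HDF5-based,
# handled through a bundled Python/h5py helper) and a documented CSV
# dialect convenient for tests and spreadsheets.

snirf_helper <- function() {
  path <- system.file("python", "snirf_io.py", package = "optoflow")
  if (path == "") stop("snirf bridge script not found in the installed package")
  path
}

run_snirf_bridge <- function(mode, src, dst) {
  out <- suppressWarnings(
    system2("python", c(snirf_helper(), mode, shQuote(src), shQuote(dst)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    msg <- paste(out, collapse = "\n")
    if (grepl("unsupported-format", msg)) {
      stop("read_snirf: unsupported format - ", sub(".*unsupported-format: ?", "", msg))
    }
    stop("SNIRF bridge failed (", mode, "): ", msg)
  }
  invisible(TRUE)
}

recording_to_payload <- function(rec) {
  d <- dim(rec$intensity)
  cols <- vector("list", d[2] * 2)
  k <- 0
  for (ch in seq_len(d[2])) for (w in 1:2) {
    k <- k + 1
    cols[[k]] <- rec$intensity[, ch, w]
  }
  list(
    fs = rec$fs,
    subject_age = rec$subject_age,
    wavelengths = I(rec$layout$wavelengths),
    channels = lapply(as.list(rec$layout$channels), I),
    roi_channels = I(rec$layout$roi_channels),
    stim = list(name = "Tap",
                onsets = I(rec$stimulus$onsets),
                task_duration = rec$stimulus$task_duration,
                rest_duration = rec$stimulus$rest_duration),
    intensity = lapply(cols, I)
  )
}

payload_to_recording <- function(p) {
  channels <- data.frame(source_id = as.integer(p$channels$source_id),
                         detector_id = as.integer(p$channels$detector_id),
                         distance_mm = as.numeric(p$channels$distance_mm),
                         is_short = as.logical(p$channels$is_short))
  layout <- probe_layout(channels, wavelengths = as.numeric(p$wavelengths),
                         roi_channels = as.integer(unlist(p$roi_channels)))
  stim <- stimulus_design(as.numeric(p$stim$onsets),
                          task_duration = as.numeric(p$stim$task_duration),
                          rest_duration = as.numeric(p$stim$rest_duration))
  nc <- nrow(channels)
  cols <- p$intensity
  if (is.matrix(cols)) cols <- lapply(seq_len(nrow(cols)), function(i) cols[i, ])
  n <- length(cols[[1]])
  intensity <- array(0, c(n, nc, 2))
  k <- 0
  for (ch in seq_len(nc)) for (w in 1:2) {
    k <- k + 1
    intensity[, ch, w] <- as.numeric(cols[[k]])
  }
  if (any(intensity <= 0)) {
    stop("read_snirf: validation failed - non-positive intensity values")
  }
  raw_recording(intensity, as.numeric(p$fs), layout, stim,
                as.numeric(p$subject_age))
}

#' Write a recording to a SNIRF file
#'
#' Continuous-wave SNIRF layout: `/nirs/data1` intensity matrix with one
#' measurement-list entry per channel and wavelength, probe geometry
#' encoding each channel's source-detector distance, and one stimulus
#' group with the block onsets.
#'
#' @param rec a [raw_recording()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_snirf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  if (n_channels(rec$layout) == 0) stop("write_snirf: recording has no channels")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(recording_to_payload(rec), tmp, auto_unbox = TRUE,
                       digits = NA)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("write_snirf: directory does not exist: ", dirname(path))
  run_snirf_bridge("write", tmp, path)
  invisible(path)
}

#' Read a SNIRF recording
#'
#' Accepts continuous-wave SNIRF files with exactly two wavelengths;
#' intensity, probe geometry and block stimuli are mapped onto a
#' [raw_recording()] (wavelength planes sorted ascending; onsets in
#' seconds from the first sample).
#'
#' @param path SNIRF file path
#' @return a [raw_recording()]
#' @export
read_snirf <- function(path) {
  if (!file.exists(path)) stop("read_snirf: file not found: ", path)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  run_snirf_bridge("read", path, tmp)
  payload_to_recording(jsonlite::read_json(tmp, simplifyVector = TRUE))
}

csv_col_name <- function(ch, wl) sprintf("ch%02d_w%d", ch, round(wl))

#' Write a recording as CSV plus JSON side-car
#'
#' One intensity column per (channel, wavelength) named `chNN_w<nm>`, one
#' row per sample; sampling rate, age, stimulus and geometry go to the
#' side-car.
#'
#' @param rec a [raw_recording()]
#' @param intensity_path CSV output path
#' @param meta_path JSON side-car output path
#' @return `intensity_path`, invisibly
#' @export
write_csv_recording <- function(rec, intensity_path, meta_path) {
  stopifnot(inherits(rec, "raw_recording"))
  d <- dim(rec$intensity)
  cols <- list()
  for (ch in seq_len(d[2])) for (w in 1:2) {
    cols[[csv_col_name(ch, rec$layout$wavelengths[w])]] <- rec$intensity[, ch, w]
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, intensity_path, row.names = FALSE)
  meta <- recording_to_payload(rec)
  meta$intensity <- NULL
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(intensity_path)
}

#' Read a recording from CSV plus JSON side-car
#'
#' @param intensity_path CSV of intensity columns named `chNN_w<nm>`
#' @param meta_path JSON side-car with fs, age, stimulus and geometry
#' @return a [raw_recording()]
#' @export
read_csv_recording <- function(intensity_path, meta_path) {
  if (!file.exists(intensity_path)) {
    stop("read_csv_recording: file not found: ", intensity_path)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(intensity_path, check.names = FALSE)
  nc <- length(meta$channels$source_id)
  wls <- sort(as.numeric(meta$wavelengths))
  expected <- unlist(lapply(seq_len(nc), function(ch) {
    vapply(wls, function(wl) csv_col_name(ch, wl), character(1))
  }))
  missing_cols <- setdiff(expected, names(df))
  extra_cols <- setdiff(names(df), expected)
  if (length(missing_cols) || length(extra_cols)) {
    stop("read_csv_recording: column/metadata mismatch; missing: [",
         paste(missing_cols, collapse = ", "), "]; unexpected: [",
         paste(extra_cols, collapse = ", "), "]")
  }
  bad <- which(as.matrix(df[expected]) <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("read_csv_recording: non-positive intensity at row ", bad[1, 1],
         ", column '", expected[bad[1, 2]], "'")
  }
  p <- meta
  p$intensity <- lapply(expected, function(cn) df[[cn]])
  payload_to_recording(p)
}
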