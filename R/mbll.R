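# Modified Beer-Lambert law: intensity -> optical density -> hemoglobin
# concentration changes, with age-dependent differential path length factors.

#' Load the hemoglobin extinction-coefficient table
#'
#' Reads the versioned tabulation shipped with the package (Prahl
#' compilation, converted to natural-log units of mm^-1 per uM so that
#' distances in mm yield concentrations in uM) and returns the rows for the
#' requested wavelengths.
#'
#' @param wavelengths numeric, wavelengths in nm that must be present.
#' @param path optional path to an alternative table with columns
#'   `wavelength_nm`, `eps_hbo`, `eps_hbr`.
#' @return data.frame with one row per requested wavelength, in the
#'   requested order.
#' @export
extinction_table <- function(wavelengths = c(760, 850), path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "extinction_coefficients.csv",
                        package = "optoflow")
  }
  tab <- utils::read.csv(path, comment.char = "#")
  idx <- match(wavelengths, tab$wavelength_nm)
  if (anyNA(idx)) {
    stop("extinction_table: no coefficients for wavelength(s) ",
         paste(wavelengths[is.na(idx)], collapse = ", "), " nm")
  }
  out <- tab[idx, , drop = FALSE]
  e <- extinction_matrix(out)
  if (abs(det(e)) < 1e-12) {
    stop("extinction_table: extinction matrix is singular for this wavelength pair")
  }
  rownames(out) <- NULL
  out
}

# 2x2 matrix [wavelength x species]: rows lambda, cols (HbO, HbR)
extinction_matrix <- function(ext) {
  matrix(c(ext$eps_hbo, ext$eps_hbr), nrow = nrow(ext),
         dimnames = list(NULL, c("hbo", "hbr")))
}

#' Age- and wavelength-dependent differential path length factor
#'
#' Evaluates the general DPF equation
#' \deqn{DPF(\lambda, A) = \alpha + \beta A^{\gamma} + \delta \lambda^3 +
#'   \epsilon \lambda^2 + \zeta \lambda}
#' with the published coefficients for the frontotemporal adult/child head
#' (valid roughly for 690-900 nm light and ages 1-90 years; accuracy over
#' e.g. occipital cortex is not established). The DPF scales the geometric
#' source-detector distance to the effective photon path length.
#'
#' @param wavelength_nm wavelength in nm.
#' @param age_years subject age in years (> 0).
#' @param coef named coefficient vector `alpha, beta, gamma, delta, epsilon,
#'   zeta`; the default is the published general equation.
#' @return numeric DPF value (dimensionless, > 0)
#' @export
dpf_age <- function(wavelength_nm, age_years,
                    coef = c(alpha = 223.3, beta = 0.05624, gamma = 0.8493,
                             delta = -5.723e-7, epsilon = 0.001245,
                             zeta = -0.9025)) {
  if (any(age_years <= 0)) stop("dpf_age: age must be positive")
  val <- coef[["alpha"]] + coef[["beta"]] * age_years^coef[["gamma"]] +
    coef[["delta"]] * wavelength_nm^3 + coef[["epsilon"]] * wavelength_nm^2 +
    coef[["zeta"]] * wavelength_nm
  if (any(val <= 0)) {
    stop("dpf_age: non-positive DPF; wavelength outside model validity?")
  }
  val
}

#' Convert raw intensity to relative optical density
#'
#' Per channel and wavelength, `OD(t) = -log(I(t) / mean(I))` (natural log),
#' i.e. attenuation change relative to the mean intensity of the analyzed
#' segment.
#'
#' @param rec a [raw_recording()]
#' @return an [od_series()]
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "raw_recording"))
  if (any(rec$intensity <= 0)) {
    stop("intensity_to_od: intensities must be strictly positive")
  }
  d <- dim(rec$intensity)
  od <- rec$intensity
  for (ch in seq_len(d[2])) {
    for (w in seq_len(d[3])) {
      x <- rec$intensity[, ch, w]
      od[, ch, w] <- -log(x / mean(x))
    }
  }
  od_series(od, rec$fs, rec$layout)
}

# per-channel DPF matrix [channel x wavelength] for a recording's age/layout
dpf_for_layout <- function(layout, age_years, dpf = NULL) {
  if (is.null(dpf)) {
    dpf <- vapply(layout$wavelengths, dpf_age, numeric(1),
                  age_years = age_years)
  }
  if (length(dpf) != 2) stop("dpf must have one value per wavelength")
  dpf
}

#' Optical density to hemoglobin concentration changes
#'
#' Solves, per channel and time point, the modified Beer-Lambert system
#' \deqn{\Delta OD(\lambda) / (d \cdot DPF(\lambda)) =
#'   \epsilon_{HbO}(\lambda)\,\Delta HbO + \epsilon_{HbR}(\lambda)\,\Delta Hb}
#' for the two chromophores, using the channel's source-detector distance
#' `d` (mm) and the wavelength-specific differential path length factor.
#'
#' @param od an [od_series()]
#' @param age_years subject age (used for the DPF unless `dpf` is given).
#' @param dpf optional numeric length-2 DPF per wavelength, overriding the
#'   age model.
#' @param ext extinction table as from [extinction_table()].
#' @return a [conc_series()] in uM
#' @export
od_to_concentration <- function(od, age_years, dpf = NULL,
                                ext = extinction_table(od$layout$wavelengths)) {
  stopifnot(inherits(od, "od_series"))
  dpf <- dpf_for_layout(od$layout, age_years, dpf)
  e <- extinction_matrix(ext)
  if (abs(det(e)) < 1e-12) stop("od_to_concentration: singular extinction matrix")
  einv <- solve(e)
  d <- dim(od$od)
  hbo <- matrix(0, d[1], d[2])
  hbr <- matrix(0, d[1], d[2])
  dist <- od$layout$channels$distance_mm
  for (ch in seq_len(d[2])) {
    # pathlength-normalized OD per wavelength: [time x 2]
    odn <- sweep(od$od[, ch, , drop = TRUE], 2, dist[ch] * dpf, "/")
    conc <- odn %*% t(einv)
    hbo[, ch] <- conc[, 1]
    hbr[, ch] <- conc[, 2]
  }
  conc_series(hbo, hbr, od$fs, od$layout)
}

#' Hemoglobin concentration changes to optical density (forward model)
#'
#' Exact inverse of [od_to_concentration()]; used by the simulator to embed
#' known concentration dynamics into dual-wavelength attenuation, and by
#' round-trip checks.
#'
#' @param conc a [conc_series()] in uM
#' @param age_years,dpf,ext as in [od_to_concentration()]
#' @return an [od_series()]
#' @export
concentration_to_od <- function(conc, age_years, dpf = NULL,
                                ext = extinction_table(conc$layout$wavelengths)) {
  stopifnot(inherits(conc, "conc_series"))
  dpf <- dpf_for_layout(conc$layout, age_years, dpf)
  e <- extinction_matrix(ext)
  d <- dim(conc$hbo)
  od <- array(0, c(d[1], d[2], 2))
  dist <- conc$layout$channels$distance_mm
  for (ch in seq_len(d[2])) {
    chrom <- cbind(conc$hbo[, ch], conc$hbr[, ch])   # [time x 2]
    odn <- chrom %*% t(e)                             # [time x wavelength]
    od[, ch, ] <- sweep(odn, 2, dist[ch] * dpf, "*")
  }
  od_series(od, conc$fs, conc$layout)
}
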