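# Instrument calibrations: SMR peak heights -> buoyant mass (polystyrene
# bead standards) and baseline resonance frequency -> fluid density (NaCl
# standards). Both are simplified linear models; higher-order resonator
# response is out of scope and calibration is optional (pipelines may ingest
# buoyant masses directly).

fit_linear_calibration <- function(x, y, xlab, ylab) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop(xlab, " and ", ylab, " lengths differ")
  if (length(x) < 2L)
    stop("underdetermined calibration: need at least 2 points")
  if (length(unique(x)) < 2L)
    stop("underdetermined calibration: all ", xlab, " values are equal")
  fit <- stats::lm(y ~ x)
  list(coef = stats::coef(fit),
       residuals = stats::residuals(fit),
       rmse = sqrt(mean(stats::residuals(fit)^2)),
       n = length(x))
}

#' Fit the buoyant-mass calibration from bead standards
#'
#' Fits peak height (Hz) as a linear function of known buoyant mass (fg),
#' as done with polystyrene particle standards:
#' `peak = offset + sensitivity * mass`.
#'
#' @param peak_heights Resonance-frequency peak heights, Hz.
#' @param known_buoyant_masses Bead buoyant masses, fg.
#' @return Object of class `"mass_calibration"`: `sensitivity` (Hz/fg),
#'   `offset` (Hz), plus residuals and RMSE for QC.
#' @export
fit_mass_calibration <- function(peak_heights, known_buoyant_masses) {
  f <- fit_linear_calibration(known_buoyant_masses, peak_heights,
                              "known_buoyant_masses", "peak_heights")
  cal <- list(sensitivity = unname(f$coef[2L]), offset = unname(f$coef[1L]),
              residuals = f$residuals, rmse = f$rmse, n = f$n)
  if (cal$sensitivity == 0)
    stop("degenerate calibration: zero sensitivity")
  structure(cal, class = "mass_calibration")
}

#' Convert a peak height to buoyant mass
#'
#' Inverse of the fitted line: `mass = (peak - offset) / sensitivity`.
#'
#' @param cal A [fit_mass_calibration] result.
#' @param peak_height Peak height(s), Hz.
#' @return Buoyant mass(es), fg.
#' @export
apply_mass_calibration <- function(cal, peak_height) {
  stopifnot(inherits(cal, "mass_calibration"))
  if (any(!is.finite(peak_height))) stop("peak_height must be finite")
  (peak_height - cal$offset) / cal$sensitivity
}

#' Fit the fluid-density calibration from NaCl standards
#'
#' Fits baseline resonance frequency (Hz) as a linear function of known
#' solution density (g/cm3): `freq = intercept + slope * density`.
#'
#' @param baseline_freqs Baseline resonance frequencies, Hz.
#' @param known_densities NaCl standard densities, g/cm3.
#' @return Object of class `"density_calibration"`: `slope` (Hz per g/cm3),
#'   `intercept` (Hz), residuals and RMSE.
#' @export
fit_density_calibration <- function(baseline_freqs, known_densities) {
  f <- fit_linear_calibration(known_densities, baseline_freqs,
                              "known_densities", "baseline_freqs")
  cal <- list(slope = unname(f$coef[2L]), intercept = unname(f$coef[1L]),
              residuals = f$residuals, rmse = f$rmse, n = f$n)
  if (cal$slope == 0) stop("degenerate calibration: zero slope")
  structure(cal, class = "density_calibration")
}

#' Convert a baseline frequency to fluid density
#'
#' @param cal A [fit_density_calibration] result.
#' @param baseline_freq Baseline frequency(ies), Hz.
#' @return Fluid density(ies), g/cm3.
#' @export
apply_density_calibration <- function(cal, baseline_freq) {
  stopifnot(inherits(cal, "density_calibration"))
  if (any(!is.finite(baseline_freq))) stop("baseline_freq must be finite")
  (baseline_freq - cal$intercept) / cal$slope
}

#' @export
print.mass_calibration <- function(x, ...) {
  cat(sprintf("<mass_calibration> sensitivity %.6g Hz/fg, offset %.6g Hz (n = %d, RMSE %.3g Hz)\n",
              x$sensitivity, x$offset, x$n, x$rmse))
  invisible(x)
}

#' @export
print.density_calibration <- function(x, ...) {
  cat(sprintf("<density_calibration> slope %.6g Hz per g/cm3, intercept %.6g Hz (n = %d, RMSE %.3g Hz)\n",
              x$slope, x$intercept, x$n, x$rmse))
  invisible(x)
}
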