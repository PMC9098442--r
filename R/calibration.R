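#' Fit a weighted linear calibration curve
#'
#' Fits the linear model response = a + b * conc by weighted least squares
#' with weights 1/x (the weighting used throughout trace-level bioanalysis,
#' where variance grows with concentration), or unweighted. The returned
#' object behaves like a small fitted model: `coef()`, `predict()`,
#' `residuals()`, `summary()`, `print()` and `plot()` methods are provided,
#' and [invert_calibration()] performs inverse prediction of concentration
#' from response.
#'
#' Calibrant levels at zero concentration are incompatible with 1/x
#' weighting and are excluded with a warning. At least five distinct
#' non-zero levels are required.
#'
#' @param conc Calibrant concentrations, ng/mL.
#' @param response Instrument responses (peak area, or area ratio when
#'   internal-standard normalised).
#' @param weighting `"inverse_x"` (default) or `"none"`.
#' @param analyte,matrix Optional labels carried into the curve.
#' @param used_is Logical, whether responses are IS ratios.
#' @return An object of class `calcurve` with elements `slope`, `intercept`,
#'   `r2` (coefficient of determination of the weighted fit), `range`
#'   (lowest and highest calibrant level), `n_points`, `weighting`,
#'   `analyte`, `matrix`, `used_is` and the underlying `lm` fit.
#' @examples
#' cc <- fit_calibration(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
#' coef(cc)
#' invert_calibration(7, cc)
#' @export
fit_calibration <- function(conc, response, weighting = c("inverse_x", "none"),
                            analyte = NA_character_, matrix = NA_character_,
                            used_is = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(length(conc) == length(response))
  ok <- is.finite(conc) & is.finite(response)
  conc <- conc[ok]; response <- response[ok]
  if (weighting == "inverse_x" && any(conc <= 0)) {
    warning("excluding ", sum(conc <= 0),
            " zero/negative-concentration point(s) incompatible with 1/x weighting")
    keep <- conc > 0
    conc <- conc[keep]; response <- response[keep]
  }
  if (length(unique(conc)) < 5L)
    stop("insufficient calibration levels (need >= 5 distinct non-zero levels)",
         call. = FALSE)
  w <- if (weighting == "inverse_x") 1 / conc else rep(1, length(conc))
  fit <- stats::lm(response ~ conc, weights = w)
  # weighted coefficient of determination of the fitted objective
  ybar <- sum(w * response) / sum(w)
  ss_tot <- sum(w * (response - ybar)^2)
  r2 <- if (ss_tot > 0)
    1 - sum(w * stats::residuals(fit)^2) / ss_tot else 1
  structure(list(
    analyte = analyte, matrix = matrix,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r2 = r2,
    weighting = weighting,
    range = c(min(conc), max(conc)),
    used_is = isTRUE(used_is),
    n_points = length(conc),
    fit = fit), class = "calcurve")
}

#' @export
print.calcurve <- function(x, ...) {
  lab <- if (!is.na(x$analyte)) paste0(" ", x$analyte, " in ", x$matrix) else ""
  cat(sprintf("<calcurve>%s: response = %.6g + %.6g * conc\n", lab,
              x$intercept, x$slope))
  cat(sprintf("  weighting %s, n = %d, range %.4g-%.4g ng/mL, R2 = %.5f%s\n",
              x$weighting, x$n_points, x$range[1], x$range[2], x$r2,
              if (x$used_is) ", IS-normalised" else ""))
  invisible(x)
}

#' @export
coef.calcurve <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' Predict instrument response from concentration
#'
#' @param object A `calcurve`.
#' @param newdata Numeric vector of concentrations (ng/mL). Missing:
#'   fitted values are returned.
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.calcurve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  object$intercept + object$slope * as.numeric(newdata)
}

#' @export
residuals.calcurve <- function(object, ...) stats::residuals(object$fit)

#' @export
summary.calcurve <- function(object, ...) {
  out <- data.frame(analyte = object$analyte, matrix = object$matrix,
                    slope = object$slope, intercept = object$intercept,
                    r2 = object$r2, weighting = object$weighting,
                    range_min = object$range[1], range_max = object$range[2],
                    used_is = object$used_is, n_points = object$n_points,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.calcurve", "data.frame")
  out
}

#' @export
plot.calcurve <- function(x, ...) {
  d <- x$fit$model
  graphics::plot(d$conc, d$response, xlab = "concentration [ng/mL]",
                 ylab = "response",
                 main = if (!is.na(x$analyte)) x$analyte else "calibration", ...)
  graphics::abline(x$intercept, x$slope)
  invisible(x)
}

#' Normalise analyte responses by internal-standard areas
#'
#' For analytes mapped to an isotopically labelled internal standard the
#' response becomes the dimensionless area ratio `area / is_area`,
#' cancelling preparation and ionisation variability; unmapped analytes are
#' returned unchanged. Mapped rows without a usable IS area are dropped with
#' a warning.
#'
#' @param peaks An `xq_peaks` table.
#' @param map Named character vector, analyte name -> IS name (see
#'   [is_map()]).
#' @return The table with an added numeric `response` column and a logical
#'   `used_is` column.
#' @export
normalize_by_is <- function(peaks, map = character()) {
  stopifnot(inherits(peaks, "xq_peaks"))
  mapped <- peaks$analyte %in% names(map)
  bad <- mapped & (is.na(peaks$is_area) | peaks$is_area <= 0)
  if (any(bad)) {
    warning("dropping ", sum(bad),
            " measurement(s) with missing internal-standard area")
    peaks <- peaks[!bad, , drop = FALSE]
    mapped <- mapped[!bad]
  }
  peaks$response <- ifelse(mapped, peaks$area / peaks$is_area, peaks$area)
  peaks$used_is <- mapped
  peaks
}

#' Matrix effect as signal suppression/enhancement (SSE)
#'
#' SSE\% = 100 * slope(matrix-matched) / slope(solvent). Values below 100
#' indicate ionisation suppression by co-extracted matrix, above 100
#' enhancement.
#'
#' @param matrix_curve,solvent_curve `calcurve` objects for the same analyte
#'   fitted with the same weighting and IS usage.
#' @return SSE in percent.
#' @export
compute_sse <- function(matrix_curve, solvent_curve) {
  stopifnot(inherits(matrix_curve, "calcurve"),
            inherits(solvent_curve, "calcurve"))
  if (matrix_curve$weighting != solvent_curve$weighting ||
      matrix_curve$used_is != solvent_curve$used_is)
    stop("curves differ in weighting or IS usage", call. = FALSE)
  if (!is.na(matrix_curve$analyte) && !is.na(solvent_curve$analyte) &&
      matrix_curve$analyte != solvent_curve$analyte)
    stop("curves are for different analytes", call. = FALSE)
  if (!is.finite(solvent_curve$slope) || solvent_curve$slope <= 0)
    stop("unusable solvent calibration", call. = FALSE)
  100 * matrix_curve$slope / solvent_curve$slope
}

#' Estimate LOD and LOQ from calibrant signal-to-noise
#'
#' The limit of detection and quantitation are the concentrations at which
#' the signal-to-noise ratio reaches 3 and 10 respectively. S/N per point is
#' `(area - intercept) / noise` using the per-measurement noise estimate;
#' per level the mean S/N is used. The limit is the concentration where a
#' log-log linear fit of mean S/N against concentration crosses the
#' threshold (`method = "interpolated"`), which is exact for a
#' proportional S/N response and, unlike reporting the lowest qualifying
#' calibrant level, is not upward-biased by the additive noise floor near
#' the limit. When only one level carries a positive S/N, the lowest level
#' meeting the threshold is reported (`method = "lowest-level"`).
#'
#' @param conc Calibrant concentrations, ng/mL.
#' @param area Peak areas.
#' @param noise Per-measurement noise estimates (> 0).
#' @param intercept Baseline response subtracted from areas before the S/N
#'   ratio, default 0.
#' @param analyte,matrix Optional labels.
#' @return A list of class `sensitivity_estimate`: `analyte`, `matrix`,
#'   `lod`, `loq` (ng/mL), `method` (per limit).
#' @export
estimate_lod_loq <- function(conc, area, noise, intercept = 0,
                             analyte = NA_character_, matrix = NA_character_) {
  stopifnot(length(conc) == length(area), length(conc) == length(noise))
  if (any(is.na(noise)) || any(noise <= 0))
    stop("S/N undefined: per-point noise must be present and > 0",
         call. = FALSE)
  snr <- (area - intercept) / noise
  lev <- sort(unique(conc))
  snr_lev <- vapply(lev, function(l) mean(snr[conc == l]), 0)
  if (all(snr_lev < 3))
    stop("analyte not detectable in this design (all S/N < 3)", call. = FALSE)

  pos <- snr_lev > 0 & lev > 0
  limit_at <- function(threshold) {
    meets <- snr_lev >= threshold
    if (sum(pos) < 2L) {
      if (any(meets))
        return(list(value = min(lev[meets]), method = "lowest-level"))
      return(list(value = NA_real_, method = "none"))
    }
    f <- stats::lm(log(snr_lev[pos]) ~ log(lev[pos]))
    b <- stats::coef(f)
    if (!is.finite(b[2L]) || b[2L] <= 0) {
      if (any(meets))
        return(list(value = min(lev[meets]), method = "lowest-level"))
      return(list(value = NA_real_, method = "none"))
    }
    list(value = unname(exp((log(threshold) - b[1L]) / b[2L])),
         method = "interpolated")
  }
  loq <- limit_at(10)
  lod <- limit_at(3)
  structure(list(analyte = analyte, matrix = matrix,
                 lod = lod$value, loq = loq$value,
                 lod_method = lod$method, loq_method = loq$method),
            class = "sensitivity_estimate")
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("<sensitivity_estimate> %s in %s: LOD %.4g (%s), LOQ %.4g (%s) ng/mL\n",
              x$analyte, x$matrix, x$lod, x$lod_method, x$loq, x$loq_method))
  invisible(x)
}

#' Average sensitivity estimates across validation runs
#'
#' LOD/LOQ are estimated once per validation run; the reporting value is the
#' arithmetic mean across runs ("average LOQ"), which also drives the
#' conditional recovery-correction rule during quantitation.
#'
#' @param estimates A list of `sensitivity_estimate` objects for one
#'   analyte/matrix.
#' @return A single `sensitivity_estimate` with averaged limits.
#' @export
average_sensitivity <- function(estimates) {
  stopifnot(length(estimates) >= 1L,
            all(vapply(estimates, inherits, TRUE, "sensitivity_estimate")))
  structure(list(analyte = estimates[[1L]]$analyte,
                 matrix = estimates[[1L]]$matrix,
                 lod = mean(vapply(estimates, `[[`, 0, "lod")),
                 loq = mean(vapply(estimates, `[[`, 0, "loq")),
                 lod_method = "averaged", loq_method = "averaged"),
            class = "sensitivity_estimate")
}
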