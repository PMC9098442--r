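#' Inverse-predict concentration from instrument response
#'
#' @param response Instrument response (area or IS ratio).
#' @param curve A [fit_calibration()] `calcurve`.
#' @return Concentration in ng/mL; negative inverse predictions are floored
#'   at 0 (censoring against the LOD is handled by [censor()]).
#' @export
invert_calibration <- function(response, curve) {
  stopifnot(inherits(curve, "calcurve"))
  if (!is.finite(curve$slope) || curve$slope == 0)
    stop("calibration slope is zero; curve unusable", call. = FALSE)
  pmax(0, (response - curve$intercept) / curve$slope)
}

#' Conditional extraction-recovery correction
#'
#' Detected concentrations are divided by the analyte's average extraction
#' recovery only when the detection is reliable: concentration above the
#' average LOQ from method validation, or signal-to-noise above 10.
#' Below that the raw value is reported uncorrected.
#'
#' @param conc Detected concentration, ng/mL.
#' @param avg_recovery Average extraction recovery as a fraction in
#'   (0, 1.2].
#' @param avg_loq Average LOQ from method validation, ng/mL.
#' @param snr Signal-to-noise ratio of the observation (NA if unknown).
#' @return A list with `conc` (possibly corrected) and `recovery_corrected`.
#' @export
apply_recovery_rule <- function(conc, avg_recovery, avg_loq, snr = NA_real_) {
  if (!is.finite(avg_recovery) || avg_recovery <= 0)
    stop("avg_recovery must be > 0", call. = FALSE)
  if (avg_recovery > 1.2)
    warning("avg_recovery ", avg_recovery, " exceeds the accepted 120% ceiling")
  eligible <- (is.finite(conc) && conc > avg_loq) ||
    (is.finite(snr) && snr > 10)
  if (eligible)
    list(conc = conc / avg_recovery, recovery_corrected = TRUE)
  else
    list(conc = conc, recovery_corrected = FALSE)
}

#' Censoring status of a quantitation result
#'
#' Statuses partition the concentration axis: at or above the LOQ (or
#' signal-to-noise above 10) a value is `quantified`; from the LOD up to
#' (but excluding) the LOQ it is `below_loq`; below the LOD it is
#' `below_lod`; above the calibrated range it is `above_range` and not
#' reported numerically. The boundary convention is closed on the right:
#' exactly at the LOQ counts as quantified, exactly at the LOD as
#' below_loq.
#'
#' @param conc Concentration, ng/mL.
#' @param lod,loq Limits of detection and quantitation, ng/mL (lod <= loq).
#' @param snr Signal-to-noise ratio (optional).
#' @param upper Top of the calibrated range, ng/mL (optional; no
#'   above-range check when NA).
#' @return One of `"quantified"`, `"below_loq"`, `"below_lod"`,
#'   `"above_range"`.
#' @export
censor <- function(conc, lod, loq, snr = NA_real_, upper = NA_real_) {
  stopifnot(lod <= loq)
  if (is.finite(upper) && conc > upper) return("above_range")
  if (conc >= loq || (is.finite(snr) && snr > 10)) return("quantified")
  if (conc >= lod) return("below_loq")
  "below_lod"
}

#' Substitute a censored value for downstream statistics or intake
#'
#' Two conventions are supported: half the LOQ for descriptive statistics
#' and distribution plots, and the full LOQ for upper-bound intake
#' estimation; `zero` gives a lower-bound convention. Quantified values pass
#' through unchanged.
#'
#' @param value Numeric concentration (ignored for censored records).
#' @param status Censor status as returned by [censor()].
#' @param loq LOQ, ng/mL.
#' @param policy `"half_loq"`, `"at_loq"` or `"zero"`.
#' @return Substituted concentration, ng/mL.
#' @export
substitute_censored <- function(value, status, loq,
                                policy = c("half_loq", "at_loq", "zero")) {
  policy <- match.arg(policy)
  censored <- status %in% c("below_loq", "below_lod")
  sub <- switch(policy, half_loq = loq / 2, at_loq = loq, zero = 0)
  ifelse(censored, sub, value)
}

#' Determine system-blank contamination by solvent regression
#'
#' Contamination introduced during sample preparation (extractables and
#' leachables from tubes and the LC system) is estimated as the mean
#' concentration of triplicate analytical water blanks read off the solvent
#' calibration.
#'
#' @param blank_areas Peak areas of the system blanks (>= 3 values).
#' @param solvent_curve Solvent `calcurve`.
#' @return Contamination concentration, ng/mL.
#' @export
blank_contamination <- function(blank_areas, solvent_curve) {
  if (length(blank_areas) < 3L)
    stop("need >= 3 system blanks", call. = FALSE)
  mean(invert_calibration(blank_areas, solvent_curve))
}

#' Blank-correct quantitation results
#'
#' Subtracts the system contamination (see [blank_contamination()]) from the
#' concentrations of analytes flagged `blank_correct` in the panel, flooring
#' at zero; other analytes are untouched (a warning is logged if their
#' blanks are visibly contaminated). Method-validation results are corrected
#' with the same value upstream.
#'
#' @param results A data frame with columns `analyte` and `conc`.
#' @param contamination Named numeric vector of contamination levels
#'   (ng/mL) per analyte, from [blank_contamination()].
#' @param panel An `xq_panel`.
#' @return `results` with corrected `conc` plus logical `blank_corrected`
#'   and numeric `blank_subtracted` columns.
#' @export
blank_correct <- function(results, contamination, panel) {
  stopifnot(is.data.frame(results), inherits(panel, "xq_panel"))
  flagged <- vapply(panel, `[[`, TRUE, "blank_correct")
  flagged_names <- names(panel)[flagged]
  need <- intersect(flagged_names, unique(results$analyte))
  missing_bl <- setdiff(need, names(contamination))
  if (length(missing_bl))
    stop("flagged analyte(s) without system blanks: ",
         paste(missing_bl, collapse = ", "), call. = FALSE)
  hot_unflagged <- setdiff(names(contamination)[contamination > 0],
                           flagged_names)
  if (length(hot_unflagged))
    warning("contaminated blanks for unflagged analyte(s), not corrected: ",
            paste(hot_unflagged, collapse = ", "))
  sub <- ifelse(results$analyte %in% flagged_names,
                unname(contamination[results$analyte]), 0)
  sub[is.na(sub)] <- 0
  results$blank_subtracted <- pmin(sub, results$conc)
  results$conc <- pmax(0, results$conc - sub)
  results$blank_corrected <- sub > 0 | results$analyte %in% flagged_names
  results
}

#' Quantify unknown samples against fitted calibrations
#'
#' Full quantitation chain for a peak table: internal-standard
#' normalisation, inverse prediction from the analyte's matrix-matched
#' curve, solvent-regression blank correction for flagged analytes,
#' censoring against average LOD/LOQ with the signal-to-noise override, and
#' conditional recovery correction.
#'
#' @param peaks `xq_peaks` table; rows with `role == "unknown"` are
#'   quantified, rows with `role == "system_blank"` supply the blanks.
#' @param curves Named list of `calcurve`s keyed `"analyte|matrix"`
#'   (see [calibrate_batch()]).
#' @param sensitivities Named list of `sensitivity_estimate`s keyed by
#'   analyte.
#' @param recoveries Named numeric vector of average extraction recoveries
#'   (fractions) per analyte; analytes absent from it are not corrected.
#' @param panel An `xq_panel`.
#' @return A data frame of class `xq_quant`: one row per unknown
#'   measurement with `conc` (ng/mL, NA below LOD), `status`, `snr`,
#'   `recovery_corrected`, `blank_corrected`, `blank_subtracted`.
#' @export
quantify_unknowns <- function(peaks, curves, sensitivities,
                              recoveries = numeric(), panel) {
  stopifnot(inherits(peaks, "xq_peaks"))
  peaks <- normalize_by_is(peaks, is_map(panel))
  unk <- peaks[peaks$role == "unknown", , drop = FALSE]
  if (!nrow(unk)) stop("no unknown measurements in table", call. = FALSE)

  # contamination per flagged analyte from system blanks via solvent curves
  contamination <- numeric()
  flagged <- names(panel)[vapply(panel, `[[`, TRUE, "blank_correct")]
  bl <- peaks[peaks$role == "system_blank" & peaks$analyte %in% flagged, ,
              drop = FALSE]
  for (a in unique(bl$analyte)) {
    sc <- curves[[paste0(a, "|solvent")]]
    if (is.null(sc)) next
    contamination[[a]] <- blank_contamination(bl$response[bl$analyte == a],
                                              sc)
  }

  n <- nrow(unk)
  out <- data.frame(sample_id = unk$sample_id, analyte = unk$analyte,
                    matrix = unk$matrix, conc = NA_real_,
                    status = NA_character_, snr = NA_real_,
                    recovery_corrected = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a <- unk$analyte[i]
    spec <- panel[[a]]
    if (is.null(spec)) stop("analyte not in panel: ", a, call. = FALSE)
    mx <- lookup_matrix(unk$matrix[i], spec$calibration_matrix)
    curve <- curves[[paste0(a, "|", mx)]]
    if (is.null(curve))
      stop("quantitation: no calibration for ", a, " in ", mx, call. = FALSE)
    out$conc[i] <- invert_calibration(unk$response[i], curve)
    # S/N is always on raw instrument signal; the curve intercept is only
    # comparable when the response is the raw area
    if (!is.na(unk$noise[i]))
      out$snr[i] <- (unk$area[i] -
                       if (curve$used_is) 0 else curve$intercept) /
        unk$noise[i]
  }
  out <- blank_correct(out, contamination, panel)

  for (i in seq_len(n)) {
    a <- out$analyte[i]
    sens <- sensitivities[[a]]
    if (is.null(sens)) stop("no sensitivity estimate for ", a, call. = FALSE)
    curve <- curves[[paste0(a, "|",
                            lookup_matrix(out$matrix[i],
                                          panel[[a]]$calibration_matrix))]]
    out$status[i] <- censor(out$conc[i], sens$lod, sens$loq, out$snr[i],
                            upper = curve$range[2L])
    if (out$status[i] == "quantified" && a %in% names(recoveries)) {
      rc <- apply_recovery_rule(out$conc[i], recoveries[[a]], sens$loq,
                                out$snr[i])
      out$conc[i] <- rc$conc
      out$recovery_corrected[i] <- rc$recovery_corrected
    }
    if (out$status[i] == "below_lod") out$conc[i] <- NA_real_
    if (out$status[i] == "above_range") out$conc[i] <- NA_real_
  }
  class(out) <- c("xq_quant", "data.frame")
  out
}

# serum and plasma share calibration; warn once per session pair elsewhere
lookup_matrix <- function(sample_matrix, calibration_matrix) {
  if (sample_matrix == "plasma" && calibration_matrix == "serum")
    return("serum")
  calibration_matrix
}

#' @export
print.xq_quant <- function(x, ...) {
  cat("<xq_quant> ", nrow(x), " results; status: ", sep = "")
  print(table(x$status))
  invisible(x)
}
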