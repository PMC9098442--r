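#' Extraction recovery in percent
#'
#' @param measured_conc Detected concentration, ng/mL (before any recovery
#'   correction).
#' @param spiked_conc Spiked nominal concentration, ng/mL (> 0).
#' @return Recovery, percent.
#' @export
recovery <- function(measured_conc, spiked_conc) {
  if (any(spiked_conc <= 0)) stop("spiked_conc must be > 0", call. = FALSE)
  100 * measured_conc / spiked_conc
}

#' Relative standard deviation in percent
#'
#' Sample standard deviation (n - 1 denominator) over the mean.
#'
#' @param values Numeric vector, n >= 2, non-zero mean.
#' @return RSD, percent.
#' @export
precision_rsd <- function(values) {
  if (length(values) < 2L) stop("need n >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; RSD undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Horwitz reference tolerance for intermediate precision
#'
#' The Horwitz equation RSD\% = 2^(1 - 0.5 log10 C) with C the dimensionless
#' mass fraction; concentrations in ng/mL are converted with the
#' water-density convention (1 ng/mL = 1e-9 g/g). At trace levels it yields
#' 45\% (1 ng/mL), 64\% (0.1 ng/mL) and 91\% (0.01 ng/mL).
#'
#' @param conc Concentration, ng/mL (> 0).
#' @return Tolerated RSD, percent.
#' @export
horwitz_rsd <- function(conc) {
  if (any(conc <= 0)) stop("conc must be > 0", call. = FALSE)
  2^(1 - 0.5 * log10(conc * 1e-9))
}

#' Tiered in-house precision limit
#'
#' Horwitz tolerances are very permissive at trace level, so stricter
#' stepwise limits apply: 32\% below 10 ng/mL, 27\% from 10 to 100 ng/mL,
#' 23\% from 100 to 1000 ng/mL and 16\% above 1000 ng/mL. The same limits
#' are used for intermediate precision and repeatability.
#'
#' @param conc Concentration, ng/mL (> 0).
#' @return Maximum acceptable RSD, percent.
#' @export
custom_precision_limit <- function(conc) {
  stopifnot(all(conc > 0))
  ifelse(conc < 10, 32,
         ifelse(conc < 100, 27,
                ifelse(conc < 1000, 23, 16)))
}

#' Selectivity check against blank interference
#'
#' An analyte/matrix combination fails selectivity when the mean response of
#' either triplicate blank kind exceeds a fraction of the lowest calibrant's
#' response (default 30\%) at the analyte's retention window.
#'
#' @param matrix_blanks,system_blanks Blank responses, >= 3 each.
#' @param reference_response Response of the lowest calibrant level.
#' @param threshold Fraction of `reference_response` tolerated, default 0.3.
#' @return Logical: TRUE when selective (pass).
#' @export
check_selectivity <- function(matrix_blanks, system_blanks,
                              reference_response, threshold = 0.30) {
  if (length(matrix_blanks) < 3L || length(system_blanks) < 3L)
    stop("need triplicate matrix and system blanks", call. = FALSE)
  stopifnot(reference_response > 0)
  mean(matrix_blanks) <= threshold * reference_response &&
    mean(system_blanks) <= threshold * reference_response
}

#' Evaluate the validation criteria for one analyte/matrix/level record
#'
#' Pass/fail verdicts: recovery within 50-120\%, intermediate precision and
#' repeatability RSD at or below the tiered limit for the level's nominal
#' concentration, weighted R-squared above 0.9, and selectivity. A missing
#' metric is marked `"not evaluable"` and blocks `fulfils_all`.
#'
#' @param record List or one-row data frame with `recovery_pct`,
#'   `intermediate_precision_rsd`, `repeatability_rsd`, `r2`,
#'   `selectivity_ok` and `level_conc` (nominal spike concentration,
#'   ng/mL).
#' @return List with `criteria` (named character vector of
#'   `"pass"`/`"fail"`/`"not evaluable"`) and `fulfils_all`.
#' @export
evaluate_analyte <- function(record) {
  verdict <- function(x, ok) {
    if (is.null(x) || length(x) != 1L || is.na(x)) "not evaluable"
    else if (isTRUE(ok(x))) "pass" else "fail"
  }
  limit <- if (!is.null(record$level_conc) && is.finite(record$level_conc))
    custom_precision_limit(record$level_conc) else NA_real_
  criteria <- c(
    recovery = verdict(record$recovery_pct, function(x) x >= 50 && x <= 120),
    intermediate_precision = verdict(record$intermediate_precision_rsd,
                                     function(x) !is.na(limit) && x <= limit),
    repeatability = verdict(record$repeatability_rsd,
                            function(x) !is.na(limit) && x <= limit),
    linearity = verdict(record$r2, function(x) x > 0.9),
    selectivity = verdict(record$selectivity_ok, isTRUE))
  list(criteria = criteria, fulfils_all = all(criteria == "pass"))
}

#' Fit all calibrations of a batch and estimate sensitivities
#'
#' Fits pooled (all validation runs) weighted matrix-matched and solvent
#' curves per analyte, estimates LOD/LOQ once per run from the run's
#' matrix calibrants and averages across runs, and computes the matrix
#' effect (SSE) per run from the run-wise slope ratio.
#'
#' @param peaks An `xq_peaks` table containing `calibrant` and
#'   `solvent_calibrant` rows.
#' @param panel An `xq_panel`.
#' @param weighting Passed to [fit_calibration()].
#' @return List with `curves` (named `"analyte|matrix"`), `sensitivities`
#'   (averaged, named by analyte; zero limits when the table carries no
#'   noise estimates), `sse` (named mean SSE\% per analyte) and
#'   `per_run` (data frame of run-wise SSE and limits).
#' @export
calibrate_batch <- function(peaks, panel, weighting = "inverse_x") {
  stopifnot(inherits(peaks, "xq_peaks"), inherits(panel, "xq_panel"))
  peaks <- normalize_by_is(peaks, is_map(panel))
  curves <- list(); sens <- list(); sse <- numeric(); per_run <- list()
  for (a in intersect(names(panel), unique(peaks$analyte))) {
    mx <- panel[[a]]$calibration_matrix
    cal_m <- peaks[peaks$analyte == a & peaks$role == "calibrant", ,
                   drop = FALSE]
    cal_s <- peaks[peaks$analyte == a & peaks$role == "solvent_calibrant", ,
                   drop = FALSE]
    if (!nrow(cal_m)) stop("no matrix calibrants for ", a, call. = FALSE)
    cm <- fit_calibration(cal_m$nominal_conc, cal_m$response,
                          weighting = weighting, analyte = a, matrix = mx,
                          used_is = any(cal_m$used_is))
    curves[[paste0(a, "|", mx)]] <- cm
    if (nrow(cal_s)) {
      cs <- fit_calibration(cal_s$nominal_conc, cal_s$response,
                            weighting = weighting, analyte = a,
                            matrix = "solvent",
                            used_is = any(cal_s$used_is))
      curves[[paste0(a, "|solvent")]] <- cs
    }
    run_sens <- list(); run_rows <- list()
    for (day in sort(unique(cal_m$day))) {
      dm <- cal_m[cal_m$day == day, , drop = FALSE]
      run_sse <- NA_real_
      if (nrow(cal_s)) {
        ds <- cal_s[cal_s$day == day, , drop = FALSE]
        if (nrow(ds) >= 5L && nrow(dm) >= 5L) {
          fm <- fit_calibration(dm$nominal_conc, dm$response,
                                weighting = weighting, analyte = a,
                                matrix = mx, used_is = any(dm$used_is))
          fs <- fit_calibration(ds$nominal_conc, ds$response,
                                weighting = weighting, analyte = a,
                                matrix = "solvent",
                                used_is = any(ds$used_is))
          run_sse <- compute_sse(fm, fs)
        }
      }
      se <- if (all(is.na(dm$noise))) NULL
      else estimate_lod_loq(dm$nominal_conc, dm$area, dm$noise,
                            intercept = if (cm$used_is) 0 else cm$intercept,
                            analyte = a, matrix = mx)
      if (!is.null(se)) run_sens[[length(run_sens) + 1L]] <- se
      run_rows[[length(run_rows) + 1L]] <- data.frame(
        analyte = a, matrix = mx, run = day, sse_pct = run_sse,
        lod = if (is.null(se)) NA_real_ else se$lod,
        loq = if (is.null(se)) NA_real_ else se$loq,
        stringsAsFactors = FALSE)
    }
    sens[[a]] <- if (length(run_sens)) average_sensitivity(run_sens)
    else structure(list(analyte = a, matrix = mx, lod = 0, loq = 0,
                        lod_method = "undefined", loq_method = "undefined"),
                   class = "sensitivity_estimate")
    rr <- do.call(rbind, run_rows)
    sse[[a]] <- mean(rr$sse_pct, na.rm = TRUE)
    per_run[[a]] <- rr
  }
  list(curves = curves, sensitivities = sens, sse = sse,
       per_run = do.call(rbind, c(per_run, make.row.names = FALSE)))
}

#' Run in-house method validation on a spiking batch
#'
#' Computes, per analyte/matrix/spike level: mean recovery across the nine
#' spiking results (3 replicates x 3 days, before any recovery
#' correction but after system-blank correction for flagged analytes),
#' intermediate precision (RSD, n = 9), repeatability (RSD over the six
#' same-day repeat injections, batch `"repeat"`), weighted R-squared,
#' SSE, selectivity against triplicate blanks, averaged LOD/LOQ, Horwitz
#' reference tolerance, and criterion verdicts via [evaluate_analyte()].
#'
#' @param peaks `xq_peaks` table with spike, calibrant and blank rows.
#' @param cal Result of [calibrate_batch()] on the same table.
#' @param panel An `xq_panel`.
#' @param selectivity_threshold Fraction of the lowest calibrant response
#'   tolerated in blanks, default 0.3.
#' @return List of class `xq_validation`: `records` (one row per
#'   analyte/level), `summary` (one row per matrix: percent of analytes
#'   fulfilling all criteria at >= 1 level, median recovery),
#'   `avg_recovery` (named fractions, mean across levels and days, used by
#'   the quantitation rule).
#' @export
validate_method <- function(peaks, cal, panel, selectivity_threshold = 0.30) {
  stopifnot(inherits(peaks, "xq_peaks"))
  peaks <- normalize_by_is(peaks, is_map(panel))
  rows <- list()
  for (a in intersect(names(panel), unique(peaks$analyte))) {
    mx <- panel[[a]]$calibration_matrix
    curve <- cal$curves[[paste0(a, "|", mx)]]
    sens <- cal$sensitivities[[a]]
    sp <- peaks[peaks$analyte == a & peaks$role == "spike", , drop = FALSE]
    if (!nrow(sp)) next
    contam <- 0
    sb <- peaks[peaks$analyte == a & peaks$role == "system_blank", ,
                drop = FALSE]
    if (isTRUE(panel[[a]]$blank_correct)) {
      sc <- cal$curves[[paste0(a, "|solvent")]]
      if (is.null(sc) || nrow(sb) < 3L)
        stop("flagged analyte without triplicate system blanks/solvent curve: ",
             a, call. = FALSE)
      contam <- blank_contamination(sb$response[order(sb$sample_id)][1:3], sc)
    }
    mb <- peaks[peaks$analyte == a & peaks$role == "matrix_blank", ,
                drop = FALSE]
    sel_ok <- NA
    if (nrow(mb) >= 3L && nrow(sb) >= 3L) {
      lowest <- min(curve$range)
      ref <- predict(curve, lowest) - curve$intercept
      # flagged analytes are screened on the blank residual after
      # subtracting the determined contamination response
      sc <- cal$curves[[paste0(a, "|solvent")]]
      adj_m <- contam * curve$slope
      adj_s <- if (is.null(sc)) 0 else contam * sc$slope
      sel_ok <- check_selectivity(
        pmax(0, mb$response - curve$intercept - adj_m),
        pmax(0, sb$response - (if (is.null(sc)) 0 else sc$intercept) - adj_s),
        ref, selectivity_threshold)
    }
    for (nominal in sort(unique(sp$nominal_conc))) {
      lv <- sp[sp$nominal_conc == nominal, , drop = FALSE]
      main <- lv[lv$batch != "repeat", , drop = FALSE]
      rep6 <- lv[lv$batch == "repeat", , drop = FALSE]
      meas <- pmax(0, invert_calibration(main$response, curve) - contam)
      rec <- recovery(meas, nominal)
      ip <- if (nrow(main) >= 2L) precision_rsd(meas) else NA_real_
      rp <- if (nrow(rep6) >= 2L)
        precision_rsd(pmax(0, invert_calibration(rep6$response, curve) -
                             contam)) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = a, matrix = mx, level_conc = nominal,
        n = nrow(main), recovery_pct = mean(rec),
        intermediate_precision_rsd = ip, repeatability_rsd = rp,
        r2 = curve$r2, sse_pct = unname(cal$sse[a]),
        selectivity_ok = sel_ok, lod = sens$lod, loq = sens$loq,
        horwitz_limit = horwitz_rsd(nominal),
        precision_limit = custom_precision_limit(nominal),
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, c(rows, make.row.names = FALSE))
  ev <- lapply(seq_len(nrow(records)),
               function(i) evaluate_analyte(as.list(records[i, ])))
  for (crit in c("recovery", "intermediate_precision", "repeatability",
                 "linearity", "selectivity"))
    records[[paste0("crit_", crit)]] <-
      vapply(ev, function(e) e$criteria[[crit]], "")
  records$fulfils_all <- vapply(ev, `[[`, TRUE, "fulfils_all")

  summ <- do.call(rbind, lapply(split(records, records$matrix), function(d) {
    per_analyte <- tapply(d$fulfils_all, d$analyte, any)
    data.frame(matrix = d$matrix[1L], n_analytes = length(per_analyte),
               pct_fulfilling = 100 * mean(per_analyte),
               median_recovery = stats::median(d$recovery_pct),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  avg_rec <- c(tapply(records$recovery_pct, records$analyte, mean)) / 100
  structure(list(records = records, summary = summ,
                 avg_recovery = avg_rec), class = "xq_validation")
}

#' @export
print.xq_validation <- function(x, ...) {
  cat("<xq_validation> ", nrow(x$records), " analyte/level records\n",
      sep = "")
  print(x$summary)
  invisible(x)
}
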