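#' Detection summary for one analyte in a cohort
#'
#' Counts positive samples (quantified or detected below the LOQ) and
#' reports the minimum and maximum quantified concentration; when the
#' extreme detection is censored the token `"<LOQ"` is reported instead.
#' Analytes never detected are suppressed (`NULL`).
#'
#' @param results Data frame with columns `conc` and `status` for one
#'   analyte.
#' @param cohort Cohort label.
#' @param analyte Analyte name.
#' @return A one-row data frame (`analyte`, `cohort`, `n_positive`,
#'   `min_conc`, `max_conc` as character), or `NULL` when nothing was
#'   detected.
#' @export
detection_summary <- function(results, cohort = "cohort",
                              analyte = NA_character_) {
  stopifnot(nrow(results) >= 1L)
  detected <- results$status %in% c("quantified", "below_loq")
  if (!any(detected)) return(NULL)
  q <- results$conc[results$status == "quantified"]
  q <- q[is.finite(q)]
  any_censored <- any(results$status == "below_loq")
  min_tok <- if (any_censored) "<LOQ"
  else format(min(q), digits = 3)
  max_tok <- if (length(q)) format(max(q), digits = 3) else "<LOQ"
  data.frame(analyte = analyte, cohort = cohort,
             n_positive = sum(detected), min_conc = min_tok,
             max_conc = max_tok, stringsAsFactors = FALSE)
}

#' Censoring-aware distribution quartiles
#'
#' Substitutes censored records at half the LOQ (the convention used for
#' distribution displays) and returns the first quartile, median and third
#' quartile using linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param results Data frame with `conc` and `status` for one analyte.
#' @param loq LOQ, ng/mL.
#' @param policy Substitution policy, default `"half_loq"`.
#' @return Named numeric vector `c(q1, median, q3)`.
#' @export
distribution_summary <- function(results, loq, policy = "half_loq") {
  detected <- results$status %in% c("quantified", "below_loq")
  if (!any(detected)) stop("no detections", call. = FALSE)
  vals <- substitute_censored(results$conc, results$status, loq, policy)
  q <- stats::quantile(vals, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(q1 = q[1L], median = q[2L], q3 = q[3L])
}

#' Pairwise inter-analyte correlation over a longitudinal series
#'
#' Correlates analyte concentration series over the days where both
#' analytes were measured, substituting censored days at half the
#' reporting limit. Rank correlation (Spearman) is the default, being
#' robust to the mass point that substitution creates. Cells with fewer
#' than `min_overlap` shared days, or with a constant series, are
#' unavailable (NA) rather than zero.
#'
#' @param long Data frame from [generate_longitudinal()] or equivalent,
#'   columns `day`, `analyte`, `conc`, `censored`, `reporting_limit`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param policy Substitution policy for censored days.
#' @param min_overlap Minimum shared days per cell, default 3.
#' @return List with `r` (symmetric correlation matrix, unit diagonal) and
#'   `n` (overlap count per cell).
#' @export
correlation_matrix <- function(long, method = c("spearman", "pearson"),
                               policy = "half_loq", min_overlap = 3L) {
  method <- match.arg(method)
  analytes <- unique(long$analyte)
  if (length(analytes) < 2L) stop("need >= 2 analytes", call. = FALSE)
  status <- ifelse(long$censored, "below_loq", "quantified")
  long$value <- substitute_censored(long$conc, status, long$reporting_limit,
                                    policy)
  days <- sort(unique(long$day))
  wide <- matrix(NA_real_, length(days), length(analytes),
                 dimnames = list(days, analytes))
  idx <- cbind(match(long$day, days), match(long$analyte, analytes))
  wide[idx] <- long$value
  k <- length(analytes)
  r <- matrix(NA_real_, k, k, dimnames = list(analytes, analytes))
  nmat <- matrix(0L, k, k, dimnames = list(analytes, analytes))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    nmat[i, i] <- sum(!is.na(wide[, i]))
    for (j in seq_len(k)[-seq_len(i)]) {
      ok <- !is.na(wide[, i]) & !is.na(wide[, j])
      nmat[i, j] <- nmat[j, i] <- sum(ok)
      if (sum(ok) >= min_overlap &&
          stats::sd(wide[ok, i]) > 0 && stats::sd(wide[ok, j]) > 0)
        r[i, j] <- r[j, i] <- stats::cor(wide[ok, i], wide[ok, j],
                                         method = method)
    }
  }
  list(r = r, n = nmat)
}

#' Paired comparison of treated vs untreated results
#'
#' Matches results on `sample_id` and summarises per-pair
#' treated/untreated concentration ratios by their median (e.g.
#' enzymatically deconjugated vs native aliquots, or downscaled vs full
#' sample volume). Pairs with a zero/censored denominator are excluded and
#' counted.
#'
#' @param untreated,treated Data frames with `sample_id` and `conc`.
#' @param analyte Label.
#' @return List of class `paired_comparison`: `analyte`, `n_pairs`,
#'   `ratios`, `median_ratio`, `n_excluded`.
#' @export
paired_compare <- function(untreated, treated, analyte = NA_character_) {
  m <- merge(untreated[c("sample_id", "conc")],
             treated[c("sample_id", "conc")],
             by = "sample_id", suffixes = c("_untreated", "_treated"))
  if (!nrow(m)) stop("zero matched pairs", call. = FALSE)
  ok <- is.finite(m$conc_untreated) & m$conc_untreated > 0 &
    is.finite(m$conc_treated)
  ratios <- m$conc_treated[ok] / m$conc_untreated[ok]
  structure(list(analyte = analyte, n_pairs = sum(ok), ratios = ratios,
                 median_ratio = stats::median(ratios),
                 n_excluded = sum(!ok)),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: median ratio %.3g over %d pairs (%d excluded)\n",
              x$analyte, x$median_ratio, x$n_pairs, x$n_excluded))
  invisible(x)
}

#' Normalise a concentration to a bio-fluid covariate
#'
#' Reports a level relative to urinary creatinine or blood albumin (e.g.
#' ng per mg creatinine) to compensate for dilution differences.
#'
#' @param conc Concentration, ng/mL.
#' @param covariate Covariate value in its own units (> 0).
#' @param units Unit tag recorded on the result.
#' @return Numeric vector with a `units` attribute.
#' @export
normalize_to_covariate <- function(conc, covariate,
                                   units = "ng per unit covariate") {
  if (any(covariate <= 0)) stop("covariate must be > 0", call. = FALSE)
  structure(conc / covariate, units = units)
}
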