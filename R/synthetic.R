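# Synthetic instrument/wet-lab emulation with known ground truth.
#
# Noise model per measurement: area = mu * (1 + cv * e1) + floor * e2,
# e1, e2 iid standard normal, truncated at 0 — heteroscedastic, consistent
# with the 1/x weighting used by the calibration stage. The per-measurement
# noise column equals the noise floor, so S/N = (area - intercept)/floor and
# the true LOQ (S/N = 10) has the closed form 10*floor/matrix_slope.

#' Ground truth for one analyte in one matrix
#'
#' @param analyte Analyte name.
#' @param matrix Calibration matrix.
#' @param true_slope Solvent-calibration slope, area per (ng/mL).
#' @param true_intercept Baseline area.
#' @param sse_true Matrix effect as a fraction (matrix slope / solvent
#'   slope); < 1 is suppression.
#' @param recovery_true Extraction recovery fraction in (0, 1.2].
#' @param noise_floor Additive noise floor in area units (0 = noiseless).
#' @param noise_cv Proportional noise coefficient of variation.
#' @param contamination_conc System contamination introduced during sample
#'   preparation, ng/mL (appears in blanks, spikes and unknowns).
#' @return A `truth_record` list; `loq_true`/`lod_true` are derived in
#'   closed form from the noise floor and the matrix slope.
#' @export
truth_record <- function(analyte, matrix, true_slope, true_intercept = 0,
                         sse_true = 1, recovery_true = 1,
                         noise_floor = 0, noise_cv = 0,
                         contamination_conc = 0) {
  stopifnot(true_slope > 0, sse_true > 0,
            recovery_true > 0, recovery_true <= 1.2,
            noise_floor >= 0, noise_cv >= 0, contamination_conc >= 0)
  slope_m <- true_slope * sse_true
  structure(list(analyte = analyte, matrix = matrix,
                 true_slope = true_slope, true_intercept = true_intercept,
                 sse_true = sse_true, recovery_true = recovery_true,
                 noise_floor = noise_floor, noise_cv = noise_cv,
                 contamination_conc = contamination_conc,
                 loq_true = if (noise_floor > 0) 10 * noise_floor / slope_m
                            else NA_real_,
                 lod_true = if (noise_floor > 0) 3 * noise_floor / slope_m
                            else NA_real_),
            class = "truth_record")
}

# one noisy area draw (vectorised), truncated at zero
noisy_area <- function(mu, tr) {
  n <- length(mu)
  pmax(0, mu * (1 + tr$noise_cv * stats::rnorm(n)) +
         tr$noise_floor * stats::rnorm(n))
}

#' Generate a validation/quantitation batch with known truth
#'
#' Emulates one full measurement campaign for every panel analyte:
#' matrix-matched and solvent calibration series (one per validation day)
#' spanning two decades around the true LOQ, triplicate spiking experiments
#' at two levels (multiples of the true LOQ) across three days, six
#' same-day repeat injections of the low spike (batch `"repeat"`),
#' triplicate matrix and system (water) blanks carrying the system
#' contamination, and unknown cohort samples with log-normal true
#' concentrations. Spike and unknown signals pass through the true recovery
#' and the matrix effect; all signals receive heteroscedastic noise; a
#' per-day instrument sensitivity factor (`day_effects`) multiplies every
#' signal of that day. Analytes with a mapped internal standard also get an
#' IS area (nominal 1000 area units) carrying the same day effect and
#' proportional noise, so IS normalisation cancels the day effect.
#'
#' @param panel An `xq_panel`.
#' @param truth Named list of [truth_record()]s, one per panel analyte.
#' @param design List with elements `cal_levels` (>= 5, default 7),
#'   `spike_levels` (multiples of the true LOQ, default `c(3, 30)`),
#'   `replicates` (default 3), `days` (default 3), `blanks` (default 3),
#'   `unknowns` (default 5), `repeat_injections` (default 6),
#'   `day_effects` (multiplier per day, default all 1),
#'   `unknown_meanlog_mult` (median unknown concentration as a multiple of
#'   the true LOQ, default 5) and `unknown_sdlog` (default 1). For
#'   noiseless truths (no defined LOQ) levels are anchored at 1 ng/mL.
#' @param seed Integer seed; the design skeleton is seed-invariant, only
#'   noise draws change.
#' @return A list: `peaks` (an `xq_peaks` table), `truth` (manifest data
#'   frame of all generative parameters incl. `loq_true`),
#'   `unknown_truth` (true concentrations of the unknowns), `design`,
#'   `seed`.
#' @export
generate_batch <- function(panel, truth, design = list(), seed = 1L) {
  stopifnot(inherits(panel, "xq_panel"))
  d <- utils::modifyList(list(cal_levels = 7L, spike_levels = c(3, 30),
                              replicates = 3L, days = 3L, blanks = 3L,
                              unknowns = 5L, repeat_injections = 6L,
                              day_effects = NULL,
                              unknown_meanlog_mult = 5, unknown_sdlog = 1),
                         design)
  if (d$cal_levels < 5L) stop("cal_levels must be >= 5", call. = FALSE)
  if (is.null(d$day_effects)) d$day_effects <- rep(1, d$days)
  stopifnot(length(d$day_effects) == d$days)
  missing_truth <- setdiff(names(panel), names(truth))
  if (length(missing_truth))
    stop("no truth record for: ", paste(missing_truth, collapse = ", "),
         call. = FALSE)
  set.seed(as.integer(seed))
  rows <- list()
  unknown_truth <- list()
  for (a in names(panel)) {
    tr <- truth[[a]]
    spec <- panel[[a]]
    mx <- spec$calibration_matrix
    has_is <- !is.na(spec$internal_standard)
    slope_m <- tr$true_slope * tr$sse_true
    anchor <- if (is.finite(tr$loq_true)) tr$loq_true else 1
    noise_col <- if (tr$noise_floor > 0) tr$noise_floor else NA_real_
    block <- function(ids, matrix, role, mu, nominal, day, batch) {
      f <- d$day_effects[day]
      data.frame(sample_id = ids, analyte = a, matrix = matrix, role = role,
                 area = noisy_area(mu * f, tr), noise = noise_col,
                 is_area = if (has_is)
                   pmax(0, 1000 * f * (1 + tr$noise_cv *
                                         stats::rnorm(length(mu))))
                 else NA_real_,
                 nominal_conc = nominal, day = day, batch = batch,
                 stringsAsFactors = FALSE)
    }
    # calibrants: geometric series over 2 decades, 0.5x to 50x the anchor
    lev <- anchor * 0.5 * 100^(seq(0, 1, length.out = d$cal_levels))
    for (day in seq_len(d$days)) {
      rows[[length(rows) + 1L]] <- block(
        sprintf("cal_%s_d%d_l%02d", mx, day, seq_along(lev)), mx,
        "calibrant", slope_m * lev + tr$true_intercept, lev, day,
        sprintf("run%d", day))
      rows[[length(rows) + 1L]] <- block(
        sprintf("cal_solvent_d%d_l%02d", day, seq_along(lev)), "solvent",
        "solvent_calibrant", tr$true_slope * lev + tr$true_intercept, lev,
        day, sprintf("run%d", day))
    }
    # spiking experiments: replicates x days at each level
    for (li in seq_along(d$spike_levels)) {
      nominal <- d$spike_levels[li] * anchor
      if (tr$noise_floor > 0 &&
          slope_m * tr$recovery_true * nominal / tr$noise_floor < 1)
        warning("spike indistinguishable from noise: ", a, " at level ",
                d$spike_levels[li], "x")
      mu <- slope_m * (tr$recovery_true * nominal + tr$contamination_conc) +
        tr$true_intercept
      for (day in seq_len(d$days))
        rows[[length(rows) + 1L]] <- block(
          sprintf("spike_%s_L%d_d%d_r%d", mx, li, day,
                  seq_len(d$replicates)), mx, "spike",
          rep(mu, d$replicates), nominal, day, sprintf("run%d", day))
      if (li == 1L && d$repeat_injections > 0L)
        rows[[length(rows) + 1L]] <- block(
          sprintf("repeat_%s_L1_i%d", mx, seq_len(d$repeat_injections)),
          mx, "spike", rep(mu, d$repeat_injections), nominal, 1L, "repeat")
    }
    # blanks: matrix blanks and system (water) blanks
    contam_area <- tr$true_slope * tr$contamination_conc
    rows[[length(rows) + 1L]] <- block(
      sprintf("mblank_%s_%d", mx, seq_len(d$blanks)), mx, "matrix_blank",
      rep(tr$sse_true * contam_area + tr$true_intercept, d$blanks),
      NA_real_, 1L, "blanks")
    rows[[length(rows) + 1L]] <- block(
      sprintf("sblank_%d", seq_len(d$blanks)), "water", "system_blank",
      rep(contam_area + tr$true_intercept, d$blanks), NA_real_, 1L,
      "blanks")
    # unknown cohort with log-normal exposure
    if (d$unknowns > 0L) {
      tc <- stats::rlnorm(d$unknowns,
                          meanlog = log(d$unknown_meanlog_mult * anchor),
                          sdlog = d$unknown_sdlog)
      unknown_truth[[a]] <- data.frame(
        sample_id = sprintf("unk_%03d", seq_len(d$unknowns)), analyte = a,
        true_conc = tc, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- block(
        sprintf("unk_%03d", seq_len(d$unknowns)), mx, "unknown",
        slope_m * (tr$recovery_true * tc + tr$contamination_conc) +
          tr$true_intercept, NA_real_, 1L, "cohort")
    }
  }
  peaks <- do.call(rbind, rows)
  peaks$qualifier_area <- NA_real_
  manifest <- do.call(rbind, lapply(truth[names(panel)], function(tr)
    data.frame(analyte = tr$analyte, matrix = tr$matrix,
               true_slope = tr$true_slope, true_intercept = tr$true_intercept,
               sse_true = tr$sse_true, recovery_true = tr$recovery_true,
               noise_floor = tr$noise_floor, noise_cv = tr$noise_cv,
               contamination_conc = tr$contamination_conc,
               loq_true = tr$loq_true, lod_true = tr$lod_true,
               stringsAsFactors = FALSE)))
  rownames(manifest) <- NULL
  list(peaks = peak_table(peaks), truth = manifest,
       unknown_truth = do.call(rbind, c(unknown_truth,
                                        make.row.names = FALSE)),
       design = d, seed = as.integer(seed))
}

#' Longitudinal exposure profile of one analyte
#'
#' @param analyte Analyte name.
#' @param dynamics `"constant"`, `"episodic"` (isolated spike days) or
#'   `"accumulating"` (slow autocorrelated drift hovering near its level,
#'   as for bioaccumulative compounds).
#' @param median_conc Median concentration, ng/mL.
#' @param dispersion Log-scale standard deviation.
#' @param detection_prob Fraction of days expected above the reporting
#'   limit; the limit is the matching quantile of the log-normal level
#'   distribution (overridable via `reporting_limit`).
#' @param correlation_group Optional label; profiles sharing a label draw
#'   from a shared latent day factor (common exposure source).
#' @param loading Loading on the shared factor, default 0.9.
#' @param reporting_limit Optional explicit reporting limit, ng/mL.
#' @param episode_prob,episode_magnitude Episodic dynamics: per-day
#'   Bernoulli event probability (default 0.1) and log-normal burst median
#'   multiplier (default 10).
#' @return An `exposure_profile` list.
#' @export
exposure_profile <- function(analyte, dynamics = c("constant", "episodic",
                                                   "accumulating"),
                             median_conc, dispersion = 0.5,
                             detection_prob = 1,
                             correlation_group = NA_character_,
                             loading = 0.9, reporting_limit = NULL,
                             episode_prob = 0.1, episode_magnitude = 10) {
  dynamics <- match.arg(dynamics)
  stopifnot(median_conc > 0, dispersion >= 0,
            detection_prob >= 0, detection_prob <= 1,
            loading >= 0, loading <= 1)
  structure(list(analyte = analyte, dynamics = dynamics,
                 median_conc = median_conc, dispersion = dispersion,
                 detection_prob = detection_prob,
                 correlation_group = correlation_group, loading = loading,
                 reporting_limit = reporting_limit,
                 episode_prob = episode_prob,
                 episode_magnitude = episode_magnitude),
            class = "exposure_profile")
}

#' Generate a longitudinal per-day concentration series
#'
#' Emulates repeated sampling of one subject (e.g. daily breast-milk
#' collection): each analyte follows its [exposure_profile()] dynamics,
#' profiles in a shared `correlation_group` co-vary through a common latent
#' day factor, days below the analyte's reporting limit are emitted as
#' censored, and the sampling schedule can be irregularly thinned.
#'
#' @param profiles List of [exposure_profile()]s.
#' @param n_days Number of days (>= 1).
#' @param sampling_gaps Logical; when TRUE days are randomly dropped
#'   (kept with probability 0.75) to mimic an irregular schedule.
#' @param seed Integer seed.
#' @return Data frame with columns `day`, `analyte`, `conc` (NA when
#'   censored), `true_conc`, `censored`, `reporting_limit`.
#' @export
generate_longitudinal <- function(profiles, n_days, sampling_gaps = FALSE,
                                  seed = 1L) {
  stopifnot(n_days >= 1)
  set.seed(as.integer(seed))
  groups <- unique(stats::na.omit(vapply(profiles, `[[`, "",
                                         "correlation_group")))
  z <- matrix(stats::rnorm(n_days * max(1L, length(groups))),
              nrow = n_days,
              dimnames = list(NULL, if (length(groups)) groups else "g"))
  out <- list()
  for (p in profiles) {
    eps <- stats::rnorm(n_days)
    lat <- if (!is.na(p$correlation_group))
      p$loading * z[, p$correlation_group] +
        sqrt(1 - p$loading^2) * eps else eps
    if (p$dynamics == "accumulating") {
      # AR(1), phi = 0.95, stationary unit variance: slow drift
      ar <- numeric(n_days)
      ar[1L] <- lat[1L]
      for (i in seq_len(n_days)[-1L])
        ar[i] <- 0.95 * ar[i - 1L] + sqrt(1 - 0.95^2) * lat[i]
      lat <- ar
    }
    conc <- p$median_conc * exp(p$dispersion * lat)
    if (p$dynamics == "episodic") {
      burst <- stats::runif(n_days) < p$episode_prob
      mag <- exp(stats::rnorm(n_days, log(p$episode_magnitude), 0.5))
      conc <- conc * ifelse(burst, mag, 1)
    }
    rl <- if (!is.null(p$reporting_limit)) p$reporting_limit
    else if (p$detection_prob >= 1) 0
    else if (p$detection_prob <= 0) Inf
    else stats::qlnorm(1 - p$detection_prob, log(p$median_conc),
                       max(p$dispersion, 1e-12))
    censored <- conc < rl
    out[[length(out) + 1L]] <- data.frame(
      day = seq_len(n_days), analyte = p$analyte,
      conc = ifelse(censored, NA_real_, conc), true_conc = conc,
      censored = censored, reporting_limit = rl, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  if (sampling_gaps) {
    keep_day <- seq_len(n_days)[stats::runif(n_days) < 0.75]
    res <- res[res$day %in% keep_day, , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}
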