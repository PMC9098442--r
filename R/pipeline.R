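# Pipeline driver: chains simulate -> calibrate -> validate -> quantify ->
# assess -> summarize from a single YAML run configuration, with every
# random stage seeded from one recorded master seed.

write_report <- function(df, path) {
  out <- as.data.frame(df)
  num <- vapply(out, is.numeric, TRUE) & !vapply(out, is.integer, TRUE)
  for (col in names(out)[num]) out[[col]] <- format_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

stage_seed <- function(seed, k) (as.integer(seed) * 101L + k) %% 2147483629L

truth_from_config <- function(entries) {
  tr <- lapply(entries, function(e)
    truth_record(analyte = e$analyte, matrix = e$matrix %||% "milk",
                 true_slope = e$true_slope,
                 true_intercept = e$true_intercept %||% 0,
                 sse_true = e$sse_true %||% 1,
                 recovery_true = e$recovery_true %||% 1,
                 noise_floor = e$noise_floor %||% 0,
                 noise_cv = e$noise_cv %||% 0,
                 contamination_conc = e$contamination_conc %||% 0))
  names(tr) <- vapply(tr, `[[`, "", "analyte")
  tr
}

profiles_from_config <- function(entries) {
  lapply(entries, function(e)
    exposure_profile(analyte = e$analyte,
                     dynamics = e$dynamics %||% "constant",
                     median_conc = e$median_conc,
                     dispersion = e$dispersion %||% 0.5,
                     detection_prob = e$detection_prob %||% 1,
                     correlation_group = e$correlation_group %||%
                       NA_character_,
                     loading = e$loading %||% 0.9))
}

#' Run the full processing pipeline from a configuration file
#'
#' Executes the requested stages in their pipeline order — simulation of a
#' measurement batch (and optionally a longitudinal series), calibration
#' (curves, LOD/LOQ, matrix effects), method validation, quantitation of
#' unknowns, exposure assessment and cohort summaries — writing one
#' delimited report per stage plus a JSON run manifest recording the master
#' seed. Outputs are a pure function of (config, seed). Note that method
#' validation runs before quantitation because the conditional recovery
#' correction consumes the validated average recoveries.
#'
#' @param config Path to a YAML run configuration (see
#'   `inst/extdata/demo_run.yaml`) or an equivalent list. Relative paths
#'   inside the file resolve against its directory.
#' @param out_dir Output directory, created if needed.
#' @param seed Master seed; overrides the config's `seed`.
#' @return Invisibly, a named list of the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg_dir <- "."
  if (is.character(config)) {
    cfg_dir <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(seed %||% config$seed %||% 1L)
  stages <- config$stages %||% c("simulate", "calibrate", "validate",
                                 "quantify", "assess", "summarize")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel_path <- config$panel
  if (!file.exists(panel_path))
    panel_path <- file.path(cfg_dir, config$panel)
  panel <- load_panel(panel_path)
  res <- list(seed = seed)
  files <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_report(df, p)
    files <<- c(files, name)
  }

  peaks <- NULL
  if ("simulate" %in% stages) {
    sim_cfg <- config$simulate %||% stop("simulate stage needs a config block",
                                         call. = FALSE)
    truth <- truth_from_config(sim_cfg$truth)
    batch <- generate_batch(panel, truth, design = sim_cfg$design %||% list(),
                            seed = stage_seed(seed, 1L))
    peaks <- batch$peaks
    res$batch <- batch
    emit(batch$peaks, "peaks.csv")
    emit(batch$truth, "truth_manifest.csv")
    if (!is.null(batch$unknown_truth)) emit(batch$unknown_truth,
                                            "unknown_truth.csv")
    if (!is.null(sim_cfg$longitudinal)) {
      lcfg <- sim_cfg$longitudinal
      res$longitudinal <- generate_longitudinal(
        profiles_from_config(lcfg$profiles), n_days = lcfg$n_days %||% 90L,
        sampling_gaps = isTRUE(lcfg$sampling_gaps),
        seed = stage_seed(seed, 2L))
      emit(res$longitudinal, "longitudinal.csv")
    }
  } else if (!is.null(config$peaks)) {
    pp <- config$peaks
    if (!file.exists(pp)) pp <- file.path(cfg_dir, config$peaks)
    peaks <- read_peak_table(pp)
  }

  if ("calibrate" %in% stages) {
    if (is.null(peaks)) stop("calibrate: no peak table", call. = FALSE)
    res$cal <- calibrate_batch(peaks, panel)
    emit(do.call(rbind, lapply(res$cal$curves, summary)), "curves.csv")
    emit(data.frame(
      analyte = names(res$cal$sensitivities),
      lod = vapply(res$cal$sensitivities, `[[`, 0, "lod"),
      loq = vapply(res$cal$sensitivities, `[[`, 0, "loq"),
      sse_pct = unname(res$cal$sse[names(res$cal$sensitivities)]),
      stringsAsFactors = FALSE), "sensitivity.csv")
  }

  if ("validate" %in% stages) {
    if (is.null(res$cal)) stop("validate: run calibrate first", call. = FALSE)
    res$validation <- validate_method(peaks, res$cal, panel)
    emit(res$validation$records, "validation_records.csv")
    emit(res$validation$summary, "validation_summary.csv")
  }

  if ("quantify" %in% stages) {
    if (is.null(res$cal)) stop("quantify: run calibrate first", call. = FALSE)
    rec <- if (!is.null(res$validation)) res$validation$avg_recovery
    else numeric()
    res$quant <- quantify_unknowns(peaks, res$cal$curves,
                                   res$cal$sensitivities, rec, panel)
    emit(res$quant, "quant_results.csv")
  }

  if ("assess" %in% stages) {
    if (is.null(res$quant)) stop("assess: run quantify first", call. = FALSE)
    assumed <- list()
    for (a in unique(res$quant$analyte)) {
      ra <- res$quant[res$quant$analyte == a, , drop = FALSE]
      if (!any(ra$status %in% c("quantified", "below_loq"))) next
      ac <- assumed_concentration(ra, res$cal$sensitivities[[a]]$loq)
      assumed[[a]] <- data.frame(analyte = a, conc = ac$conc,
                                 assumed_from = ac$assumed_from,
                                 stringsAsFactors = FALSE)
    }
    if (length(assumed)) {
      res$assessment <- build_assessment_table(
        panel, do.call(rbind, c(assumed, make.row.names = FALSE)))
      emit(res$assessment, "assessment.csv")
    }
  }

  if ("summarize" %in% stages) {
    if (is.null(res$quant)) stop("summarize: run quantify first",
                                 call. = FALSE)
    det <- list(); qt <- list()
    for (a in unique(res$quant$analyte)) {
      ra <- res$quant[res$quant$analyte == a, , drop = FALSE]
      ds <- detection_summary(ra, cohort = "unknowns", analyte = a)
      if (!is.null(ds)) {
        det[[a]] <- ds
        q <- distribution_summary(ra, res$cal$sensitivities[[a]]$loq)
        qt[[a]] <- data.frame(analyte = a, q1 = q[1L], median = q[2L],
                              q3 = q[3L], stringsAsFactors = FALSE)
      }
    }
    if (length(det)) {
      emit(do.call(rbind, c(det, make.row.names = FALSE)),
           "detection_summary.csv")
      emit(do.call(rbind, c(qt, make.row.names = FALSE)), "quartiles.csv")
    }
    if (!is.null(res$longitudinal) &&
        length(unique(res$longitudinal$analyte)) >= 2L) {
      cm <- correlation_matrix(res$longitudinal)
      emit(as.data.frame(cm$r), "correlation.csv")
      emit(as.data.frame(cm$n), "correlation_n.csv")
    }
  }

  jsonlite::write_json(list(seed = seed, stages = stages, files = files,
                            package = "xenoquant",
                            version = as.character(utils::packageVersion("xenoquant"))),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
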