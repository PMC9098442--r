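#' @keywords internal
"_PACKAGE"

# Controlled vocabularies shared across the package.
XQ_CLASSES <- c("plasticizer", "PFAS", "industrial", "phytoestrogen",
                "mycoestrogen", "personal-care", "phytotoxin",
                "food-processing", "air-pollutant")
XQ_MATRICES <- c("urine", "serum", "plasma", "milk", "water", "solvent")
XQ_CAL_MATRICES <- c("urine", "serum", "milk", "solvent")
XQ_ROLES <- c("calibrant", "solvent_calibrant", "spike", "matrix_blank",
              "system_blank", "unknown")
XQ_GUIDANCE_KINDS <- c("TDI", "ADI", "BMDL10")

#' Define a single analyte panel entry
#'
#' An analyte specification records identity, chemical class, the matrix its
#' calibration is prepared in (the most sensitive matrix for that analyte),
#' an optional isotopically labelled internal-standard link, an optional
#' health-based guidance value, and whether system-blank correction applies
#' (reserved for contamination-prone compounds such as bisphenols and
#' phthalate metabolites leaching from labware).
#'
#' @param name Analyte name, unique within a panel.
#' @param chemical_class One of the controlled class vocabulary
#'   (`"plasticizer"`, `"PFAS"`, `"industrial"`, `"phytoestrogen"`,
#'   `"mycoestrogen"`, `"personal-care"`, `"phytotoxin"`,
#'   `"food-processing"`, `"air-pollutant"`).
#' @param calibration_matrix Matrix the calibration series is prepared in:
#'   `"urine"`, `"serum"`, `"milk"` or `"solvent"`.
#' @param polarity Ionisation polarity, `"positive"` or `"negative"`.
#' @param internal_standard Optional name of the labelled internal standard
#'   used to normalise this analyte's response, or `NA` for external
#'   calibration.
#' @param guidance Optional guidance value created by [guidance_value()].
#' @param blank_correct Logical; subtract system-blank contamination from
#'   results of this analyte.
#' @param is_conjugate Logical; analyte is a phase-II conjugate.
#' @return An object of class `analyte_spec` (a named list).
#' @seealso [load_panel()], [guidance_value()]
#' @export
analyte_spec <- function(name, chemical_class, calibration_matrix,
                         polarity = "positive", internal_standard = NA_character_,
                         guidance = NULL, blank_correct = FALSE,
                         is_conjugate = FALSE) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!chemical_class %in% XQ_CLASSES)
    stop("unknown chemical_class '", chemical_class, "'; allowed: ",
         paste(XQ_CLASSES, collapse = ", "), call. = FALSE)
  if (!calibration_matrix %in% XQ_CAL_MATRICES)
    stop("calibration_matrix must be one of ",
         paste(XQ_CAL_MATRICES, collapse = ", "), call. = FALSE)
  polarity <- match.arg(polarity, c("positive", "negative"))
  if (!is.null(guidance) && !inherits(guidance, "guidance_value"))
    stop("guidance must be created by guidance_value()", call. = FALSE)
  structure(list(name = name, chemical_class = chemical_class,
                 calibration_matrix = calibration_matrix,
                 polarity = polarity,
                 internal_standard = internal_standard,
                 guidance = guidance,
                 blank_correct = isTRUE(blank_correct),
                 is_conjugate = isTRUE(is_conjugate)),
            class = "analyte_spec")
}

#' Health-based guidance value
#'
#' Tolerable or acceptable daily intake (TDI/ADI) or a benchmark-dose lower
#' confidence limit for 10\% excess risk (BMDL10), in micrograms per kilogram
#' body weight per day. The kind determines the downstream risk metric:
#' TDI/ADI values are age-corrected and compared as a ratio to intake, while
#' BMDL10 values enter a margin-of-exposure calculation uncorrected.
#'
#' @param kind `"TDI"`, `"ADI"` or `"BMDL10"`.
#' @param value Positive numeric, ug/kg bw/day.
#' @param source Free-text citation tag.
#' @return An object of class `guidance_value`.
#' @export
guidance_value <- function(kind, value, source = "") {
  kind <- match.arg(kind, XQ_GUIDANCE_KINDS)
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value <= 0)
    stop("guidance value must be a single positive number", call. = FALSE)
  structure(list(kind = kind, value = as.numeric(value),
                 source = as.character(source)),
            class = "guidance_value")
}

#' @export
print.analyte_spec <- function(x, ...) {
  cat("<analyte_spec> ", x$name, " [", x$chemical_class, "], calibrated in ",
      x$calibration_matrix, sep = "")
  if (!is.na(x$internal_standard)) cat(", IS:", x$internal_standard)
  if (x$blank_correct) cat(", blank-corrected")
  if (!is.null(x$guidance))
    cat(sprintf(", %s %g ug/kg bw/day", x$guidance$kind, x$guidance$value))
  cat("\n")
  invisible(x)
}

#' Load an analyte panel from a YAML configuration
#'
#' The panel file is a YAML map with one entry per analyte under `analytes:`.
#' Each entry carries `class`, `calibration_matrix` and optionally
#' `polarity`, `internal_standard`, `blank_correct`, `is_conjugate` and a
#' `guidance:` block with `kind`, `value` (ug/kg bw/day) and `source`.
#'
#' @param path Path to the YAML panel file.
#' @return An object of class `xq_panel`: a named list of
#'   [analyte_spec()] objects.
#' @examples
#' p <- load_panel(system.file("extdata", "demo_panel.yaml",
#'                             package = "xenoquant"))
#' names(p)
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  entries <- cfg$analytes
  if (is.null(entries) || length(entries) == 0L)
    stop("empty panel", call. = FALSE)
  nms <- vapply(entries, function(e) as.character(e$name %||% ""), "")
  if (any(!nzchar(nms))) stop("panel entry without a name", call. = FALSE)
  if (anyDuplicated(nms))
    stop("duplicate analyte name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  specs <- lapply(entries, function(e) {
    g <- NULL
    if (!is.null(e$guidance))
      g <- guidance_value(e$guidance$kind, e$guidance$value,
                          e$guidance$source %||% "")
    analyte_spec(name = e$name,
                 chemical_class = e$class,
                 calibration_matrix = e$calibration_matrix,
                 polarity = e$polarity %||% "positive",
                 internal_standard = e$internal_standard %||% NA_character_,
                 guidance = g,
                 blank_correct = isTRUE(e$blank_correct),
                 is_conjugate = isTRUE(e$is_conjugate))
  })
  names(specs) <- nms
  structure(specs, class = "xq_panel")
}

#' @export
print.xq_panel <- function(x, ...) {
  cat("<xq_panel> ", length(x), " analytes\n", sep = "")
  tab <- table(vapply(x, `[[`, "", "chemical_class"))
  for (cl in names(tab)) cat("  ", cl, ": ", tab[[cl]], "\n", sep = "")
  invisible(x)
}

#' Summarise a panel as a data frame
#'
#' @param object An `xq_panel`.
#' @param ... Unused.
#' @return A data frame with one row per analyte.
#' @export
summary.xq_panel <- function(object, ...) {
  data.frame(
    analyte = vapply(object, `[[`, "", "name"),
    chemical_class = vapply(object, `[[`, "", "chemical_class"),
    calibration_matrix = vapply(object, `[[`, "", "calibration_matrix"),
    internal_standard = vapply(object, `[[`, "", "internal_standard"),
    blank_correct = vapply(object, `[[`, TRUE, "blank_correct"),
    guidance_kind = vapply(object, function(a)
      if (is.null(a$guidance)) NA_character_ else a$guidance$kind, ""),
    guidance_value = vapply(object, function(a)
      if (is.null(a$guidance)) NA_real_ else a$guidance$value, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Internal-standard map of a panel
#'
#' @param panel An `xq_panel`.
#' @return Named character vector mapping analyte name to IS name, only for
#'   analytes with a mapped internal standard.
#' @export
is_map <- function(panel) {
  m <- vapply(panel, `[[`, "", "internal_standard")
  m[!is.na(m)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
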