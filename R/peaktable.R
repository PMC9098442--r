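# Long-format peak tables: one row per integrated MRM observation.
# Mandatory columns; qualifier_area, noise, is_area, nominal_conc, day may be NA.
XQ_PEAK_COLS <- c("sample_id", "analyte", "matrix", "role", "area",
                  "qualifier_area", "noise", "is_area", "nominal_conc",
                  "day", "batch")
XQ_MANDATORY_COLS <- c("sample_id", "analyte", "matrix", "role", "area")
XQ_CONC_ROLES <- c("calibrant", "solvent_calibrant", "spike")

#' Construct and validate a peak-measurement table
#'
#' Normalises a data frame of integrated MRM peak observations to the
#' package's long format and enforces the table invariants: known matrix and
#' role vocabularies, non-negative areas, strictly positive noise estimates
#' where present, a nominal concentration (ng/mL) present exactly for
#' calibrant/spike roles, and uniqueness of (sample_id, analyte).
#'
#' @param df A data frame with at least columns `sample_id`, `analyte`,
#'   `matrix`, `role`, `area`; optional `qualifier_area`, `noise`,
#'   `is_area`, `nominal_conc`, `day`, `batch`.
#' @return The validated data frame with canonical column order, classed
#'   `xq_peaks`.
#' @export
peak_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(XQ_MANDATORY_COLS, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  for (col in setdiff(XQ_PEAK_COLS, names(df)))
    df[[col]] <- if (col == "batch") NA_character_ else NA_real_
  df <- df[XQ_PEAK_COLS]
  for (col in c("sample_id", "analyte", "matrix", "role", "batch"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("area", "qualifier_area", "noise", "is_area", "nominal_conc"))
    df[[col]] <- as.numeric(df[[col]])
  df$day <- as.integer(df$day)

  bad_matrix <- !df$matrix %in% XQ_MATRICES
  if (any(bad_matrix))
    stop("unknown matrix value(s): ",
         paste(unique(df$matrix[bad_matrix]), collapse = ", "), call. = FALSE)
  bad_role <- !df$role %in% XQ_ROLES
  if (any(bad_role))
    stop("unknown role value(s): ",
         paste(unique(df$role[bad_role]), collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$area) | df$area < 0))
    stop("areas must be finite and non-negative", call. = FALSE)
  if (any(!is.na(df$noise) & df$noise <= 0))
    stop("noise estimates must be > 0 where present", call. = FALSE)

  needs_conc <- df$role %in% XQ_CONC_ROLES
  miss <- needs_conc & (is.na(df$nominal_conc) | df$nominal_conc < 0)
  if (any(miss))
    stop("role requires nominal_conc but it is missing/negative for sample_id(s): ",
         paste(unique(df$sample_id[miss]), collapse = ", "), call. = FALSE)
  stray <- !needs_conc & !is.na(df$nominal_conc)
  if (any(stray))
    stop("nominal_conc present for non-calibrant/spike role, sample_id(s): ",
         paste(unique(df$sample_id[stray]), collapse = ", "), call. = FALSE)

  key <- paste(df$sample_id, df$analyte, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample_id, analyte) pair(s): ",
         paste(unique(df$sample_id[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("xq_peaks", "data.frame")
  df
}

#' Read a peak-measurement table from a delimited file
#'
#' Files are comma-separated UTF-8 with a header row and `.` decimal marks;
#' concentrations are always ng/mL. Every row is validated against the
#' [peak_table()] invariants.
#'
#' @param path Path to the CSV file.
#' @param sep Field delimiter, default `","`.
#' @return A validated `xq_peaks` data frame.
#' @export
read_peak_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = c("NA", ""))
  peak_table(df)
}

#' Write a peak-measurement table
#'
#' Inverse of [read_peak_table()]; round-trips losslessly at full double
#' precision (15 significant digits).
#'
#' @param x An `xq_peaks` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(x, path) {
  stopifnot(inherits(x, "xq_peaks"))
  out <- as.data.frame(x)
  for (col in c("area", "qualifier_area", "noise", "is_area", "nominal_conc"))
    out[[col]] <- format_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

# full-precision plain-format numbers for delimited output
format_num <- function(x) {
  ifelse(is.na(x), NA_character_,
         formatC(x, digits = 15, format = "g", flag = ""))
}

#' Sample metadata record
#'
#' Per-sample annotations used by reporting and covariate normalisation:
#' subject link, the sample volume actually processed (relevant when
#' limited material forces downscaling), an optional named covariate
#' (urinary creatinine in mg/dL, blood albumin in g/L) and the collection
#' day.
#'
#' @param sample_id,subject_id Identifiers.
#' @param volume_used Processed sample volume, uL (> 0).
#' @param covariate Optional single named numeric, e.g.
#'   `c(creatinine = 85)`.
#' @param collection_day Integer day.
#' @return A `sample_meta` list.
#' @export
sample_meta <- function(sample_id, subject_id = sample_id, volume_used = 200,
                        covariate = NULL, collection_day = NA_integer_) {
  if (!is.numeric(volume_used) || volume_used <= 0)
    stop("volume_used must be > 0", call. = FALSE)
  if (!is.null(covariate) &&
      (!is.numeric(covariate) || length(covariate) != 1L ||
         is.null(names(covariate))))
    stop("covariate must be a single named numeric", call. = FALSE)
  structure(list(sample_id = as.character(sample_id),
                 subject_id = as.character(subject_id),
                 volume_used = as.numeric(volume_used),
                 covariate = covariate,
                 collection_day = as.integer(collection_day)),
            class = "sample_meta")
}
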