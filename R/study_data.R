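#' Study table: per-subject CVP measurements and estimates
#'
#' The pilot-study cohort is represented as a `study_table`: a data frame with
#' one row per subject and the columns below. Jugular venous pulsation (JVP)
#' readings carry a three-way status because a bedside JVP can be measured,
#' attempted but unmeasurable (pulsation top not visible at the patient's
#' inclination), or not attempted at all; the two failure modes are kept
#' distinct because the overlap-accuracy statistic treats them differently.
#'
#' Columns:
#' \describe{
#'   \item{subject_id}{integer label, unique}
#'   \item{avg_invasive_cvp_mmhg}{time-averaged invasive CVP (mmHg)}
#'   \item{vein}{one of `"LIJ"`, `"RIJ"`, `"LEJ"`, `"REJ"`}
#'   \item{cf_n}{collapse force (N), `NA` until measured}
#'   \item{ho_cmh2o}{hydrostatic offset (cmH2O), `>= 0`}
#'   \item{jvp_mmhg}{JVP converted to mmHg, `NA` unless measured}
#'   \item{jvp_status}{`"measured"`, `"attempted_unmeasurable"`, or
#'     `"not_attempted"`}
#'   \item{cf_pred_cvp_mmhg, multi_pred_cvp_mmhg, trained_model_cvp_mmhg}{
#'     model predictions (mmHg), optional}
#'   \item{age_years, height_cm, weight_kg, sex}{demographics, optional and
#'     unused by any computation}
#' }
#' @name study_table
NULL

VEIN_LEVELS <- c("LIJ", "RIJ", "LEJ", "REJ")
JVP_STATUS_LEVELS <- c("measured", "attempted_unmeasurable", "not_attempted")
REQUIRED_COLUMNS <- c("subject_id", "avg_invasive_cvp_mmhg", "vein",
                      "cf_n", "ho_cmh2o", "jvp")
NUMERIC_COLUMNS <- c("subject_id", "avg_invasive_cvp_mmhg", "cf_n", "ho_cmh2o",
                     "cf_pred_cvp_mmhg", "multi_pred_cvp_mmhg",
                     "trained_model_cvp_mmhg", "age_years", "height_cm",
                     "weight_kg")

#' Construct and validate a study table
#'
#' @param df A data frame with the columns documented in [study_table]. The
#'   raw `jvp` column (numeric string, `"-"` for not attempted, `"X"` for
#'   attempted but unmeasurable) is parsed into `jvp_mmhg` + `jvp_status`.
#' @return A validated `study_table` data frame.
#' @export
as_study_table <- function(df) {
  if (!is.data.frame(df)) stop("expected a data frame")
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if ("jvp" %in% missing_cols &&
      all(c("jvp_mmhg", "jvp_status") %in% names(df)))
    missing_cols <- setdiff(missing_cols, "jvp")
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))

  if ("jvp" %in% names(df)) {
    raw <- trimws(as.character(df$jvp))
    status <- ifelse(raw == "-", "not_attempted",
                     ifelse(toupper(raw) == "X", "attempted_unmeasurable",
                            "measured"))
    val <- suppressWarnings(as.numeric(ifelse(status == "measured", raw, NA)))
    if (any(status == "measured" & is.na(val)))
      stop("non-numeric cell in a numeric column: jvp")
    df$jvp_mmhg <- val
    df$jvp_status <- status
    df$jvp <- NULL
  }
  for (col in intersect(NUMERIC_COLUMNS, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v) & !is.na(df[[col]])))
      stop("non-numeric cell in a numeric column: ", col)
    df[[col]] <- v
  }
  validate_study_table(df)
  class(df) <- c("study_table", "data.frame")
  df
}

validate_study_table <- function(df) {
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id")
  if (any(!is.finite(df$avg_invasive_cvp_mmhg)))
    stop("avg_invasive_cvp_mmhg must be finite")
  if (!all(df$vein %in% VEIN_LEVELS))
    stop("vein must be one of ", paste(VEIN_LEVELS, collapse = ", "))
  if (any(!is.na(df$cf_n) & df$cf_n <= 0))
    stop("collapse force must be > 0 when present")
  if (any(!is.na(df$ho_cmh2o) & df$ho_cmh2o < 0))
    stop("hydrostatic offset must be >= 0")
  if (!all(df$jvp_status %in% JVP_STATUS_LEVELS))
    stop("invalid jvp_status")
  if (any(df$jvp_status == "measured" & is.na(df$jvp_mmhg)) ||
      any(df$jvp_status != "measured" & !is.na(df$jvp_mmhg)))
    stop("jvp_mmhg must be present exactly when jvp_status == 'measured'")
  invisible(df)
}

#' Load a study table
#'
#' Reads the bundled 11-subject pilot-study table (the default), or a CSV /
#' JSON file with the same columns. In the `jvp` column, `"-"` is parsed as
#' not attempted and `"X"` as attempted but unmeasurable.
#'
#' @param source `"builtin"` for the bundled table, or a path to a `.csv` or
#'   `.json` file.
#' @return A validated [study_table].
#' @examples
#' tab <- load_study_table()
#' nrow(tab)      # 11
#' tab$cf_n[1]    # 9.73
#' @export
load_study_table <- function(source = "builtin") {
  if (identical(source, "builtin"))
    source <- system.file("extdata", "study_table.csv", package = "qcucvp",
                          mustWork = TRUE)
  if (!file.exists(source)) stop("no such file: ", source)
  df <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(source))
  } else {
    tryCatch(
      utils::read.csv(source, colClasses = "character", check.names = FALSE),
      error = function(e) stop("missing required column(s): empty file"))
  }
  if (nrow(df) == 0 || ncol(df) == 0)
    stop("missing required column(s): empty file")
  as_study_table(df)
}

#' The bundled pilot-study table
#'
#' Convenience accessor for `load_study_table("builtin")`: the 11-subject
#' cohort with invasive CVP, collapse force, hydrostatic offset, JVP, and the
#' published model predictions.
#'
#' @return A [study_table] with 11 rows.
#' @export
qcu_study_table <- function() load_study_table("builtin")

# Serialize jvp_mmhg + jvp_status back into the single sentinel-bearing
# column so writes are lossless for the original notation.
jvp_raw_column <- function(df) {
  ifelse(df$jvp_status == "not_attempted", "-",
         ifelse(df$jvp_status == "attempted_unmeasurable", "X",
                format_num(df$jvp_mmhg, 2)))
}

format_num <- function(x, digits) {
  out <- ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
  # trims trailing zeros beyond the printed precision of integer-valued cells
  out
}

#' Write a study table to CSV or JSON
#'
#' The JVP sentinel strings (`"-"` for not attempted, `"X"` for attempted but
#' unmeasurable) are preserved on write, so `load_study_table()` of the output
#' round-trips the table.
#'
#' @param table A [study_table].
#' @param path Destination path; format chosen by extension (`.json` for
#'   JSON, anything else is CSV).
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path) {
  validate_study_table(table)
  out <- as.data.frame(table)
  out$jvp <- jvp_raw_column(out)
  out$jvp_mmhg <- NULL
  out$jvp_status <- NULL
  # keep the raw jvp column in its tabular position
  lead <- intersect(c("subject_id", "avg_invasive_cvp_mmhg", "vein", "cf_n",
                      "ho_cmh2o", "cf_pred_cvp_mmhg", "multi_pred_cvp_mmhg",
                      "jvp", "trained_model_cvp_mmhg"), names(out))
  out <- out[, c(lead, setdiff(names(out), lead)), drop = FALSE]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' Back-derive the inclination angle from a hydrostatic offset
#'
#' The study records only the hydrostatic offset HO = 10 sin(theta) cmH2O
#' (with theta the inclination angle of the vein above the right atrium and a
#' fixed 10 cm distance); the angle itself is not part of the data. This
#' inverts that relation, `theta = asin(HO / 10)`. It is a reconstruction
#' under the fixed-distance assumption, not a measurement.
#'
#' @param ho_cmh2o Hydrostatic offset in cmH2O, in `[0, 10]`.
#' @return Inclination angle in degrees.
#' @export
theta_from_ho <- function(ho_cmh2o) {
  if (any(ho_cmh2o < 0 | ho_cmh2o > 10))
    stop("ho_cmh2o must be in [0, 10] to invert HO = 10 sin(theta)")
  asin(ho_cmh2o / 10) * 180 / pi
}
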