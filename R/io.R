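## Readers/writers for the tabular interchange formats. CSV throughout
## (UTF-8, "." decimal separator); full float precision on write so that
## read-write round trips are bitwise identity.

TRACE_COLS <- c("patient_id", "eye", "stimulus", "repeat_", "time_ms",
                "voltage_uV")
COHORT_COLS <- c("patient_id", "age_years", "sex", "pupil_class",
                 "compliance", "group_label", "variant_a", "variant_b")

#' Validate a long-format trace table
#'
#' Checks the six-column schema, stimulus and eye labels, and strictly
#' increasing time within each (patient, eye, stimulus, repeat) series.
#' Errors name the first offending row.
#'
#' @param df data frame to validate.
#' @return `df`, sorted by key then time, invisibly validated.
#' @export
validate_trace_table <- function(df) {
  miss <- setdiff(TRACE_COLS, names(df))
  if (length(miss)) stopf("trace table missing column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- which(!df$stimulus %in% STIMULI)
  if (length(bad)) stopf("row %d: unknown stimulus label '%s'",
                         bad[1], df$stimulus[bad[1]])
  bad <- which(!df$eye %in% EYES)
  if (length(bad)) stopf("row %d: unknown eye label '%s'",
                         bad[1], df$eye[bad[1]])
  if (any(df$repeat_ < 1)) stopf("repeat indices must be >= 1")
  ord <- order(df$patient_id, df$eye, df$stimulus, df$repeat_, df$time_ms)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  key <- interaction(df$patient_id, df$eye, df$stimulus, df$repeat_,
                     drop = TRUE)
  dup <- unsplit(lapply(split(df$time_ms, key),
                        function(t) c(FALSE, diff(t) <= 0)), key)
  if (any(dup)) stopf("row %d: time not strictly increasing within its trace",
                      which(dup)[1])
  df
}

#' Read a trace table CSV
#'
#' @param path CSV file with columns `patient_id, eye, stimulus, repeat_,
#'   time_ms, voltage_uV` (header required).
#' @return validated trace table, grouped by key and sorted by time.
#' @export
read_trace_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ## accept "repeat" as a column name (reserved word in R, mangled by read.csv)
  names(df)[names(df) %in% c("repeat", "repeat.")] <- "repeat_"
  validate_trace_table(df)
}

#' Write a trace table CSV
#'
#' @param df trace table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(df, path) {
  write_csv_full(df, path)
}

#' Validate a cohort metadata table
#'
#' @param df data frame with columns `patient_id, age_years, sex,
#'   pupil_class, compliance, group_label, variant_a, variant_b`.
#' @return validated `df`.
#' @export
validate_cohort_table <- function(df) {
  miss <- setdiff(setdiff(COHORT_COLS, c("group_label", "variant_a", "variant_b")),
                  names(df))
  if (length(miss)) stopf("cohort table missing column(s): %s",
                          paste(miss, collapse = ", "))
  dup <- duplicated(df$patient_id)
  if (any(dup)) stopf("duplicate patient_id '%s'", df$patient_id[which(dup)[1]])
  if (any(df$age_years < 0, na.rm = TRUE)) stopf("negative age_years")
  bad <- which(!df$sex %in% c("M", "F"))
  if (length(bad)) stopf("row %d: sex must be M or F", bad[1])
  bad <- which(!df$pupil_class %in% c(">=7mm", "<7mm"))
  if (length(bad)) stopf("row %d: pupil_class must be '>=7mm' or '<7mm'", bad[1])
  bad <- which(!(df$compliance %in% 1:5))
  if (length(bad)) stopf("row %d: compliance %s outside 1-5",
                         bad[1], df$compliance[bad[1]])
  if ("group_label" %in% names(df)) {
    bad <- which(!(is.na(df$group_label) | df$group_label %in% 1:3))
    if (length(bad)) stopf("row %d: group_label must be 1, 2 or 3", bad[1])
  }
  df
}

#' Read a cohort metadata CSV
#'
#' @param path CSV path.
#' @return validated cohort table.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_table(df)
}

#' Write a cohort metadata CSV
#'
#' @param df cohort table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(df, path) {
  write_csv_full(df, path)
}

## write at full double precision (17 significant digits round-trips IEEE754)
write_csv_full <- function(df, path) {
  df2 <- df
  for (cn in names(df2)) {
    if (is.double(df2[[cn]])) {
      x <- sprintf("%.17g", df2[[cn]])
      x[is.na(df2[[cn]])] <- NA
      df2[[cn]] <- x
    }
  }
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write pipeline result files
#'
#' Writes a deterministic file set: measurement CSVs (eye and patient
#' level), predictions CSV, coefficient CSV and a metrics JSON, for those
#' components present in `results`.
#'
#' @param results named list; recognised entries: `measurements`
#'   (list with `eye`, `patient`), `predictions` (data frame),
#'   `coefficients` (data frame), `metrics` (list, written as JSON).
#' @param dir output directory (created if needed).
#' @return character vector of files written.
#' @export
write_outputs <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  w <- function(obj, file, fun) {
    p <- file.path(dir, file)
    fun(obj, p)
    written <<- c(written, p)
  }
  if (!is.null(results$measurements)) {
    w(results$measurements$eye, "components_eye.csv", write_csv_full)
    w(results$measurements$patient, "components_patient.csv", write_csv_full)
  }
  if (!is.null(results$predictions))
    w(results$predictions, "predictions.csv", write_csv_full)
  if (!is.null(results$coefficients))
    w(results$coefficients, "coefficients.csv", write_csv_full)
  if (!is.null(results$metrics)) {
    p <- file.path(dir, "metrics.json")
    jsonlite::write_json(results$metrics, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <- c(written, p)
  }
  written
}
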