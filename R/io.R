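#' Construct a raw PPG record
#'
#' @param samples numeric vector of light-intensity samples (device counts).
#' @param fs sampling rate, Hz.
#' @param measurement_id,subject_id opaque identifiers.
#' @return An object of class `"ppg_record"`.
#' @export
ppg_record <- function(samples, fs = 50, measurement_id = "M01",
                       subject_id = "S01") {
  if (!is.numeric(samples) || any(!is.finite(samples))) {
    abort("`samples` must be finite numeric", class = "ppgbp_input_error")
  }
  assert_scalar_num(fs, "fs", lo = 1e-9)
  structure(list(samples = as.numeric(samples), fs = fs,
                 measurement_id = measurement_id, subject_id = subject_id),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record %s/%s: %d samples @ %g Hz (%.1f s)>\n",
              x$subject_id, x$measurement_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Read a raw PPG text dump
#'
#' The device format is one sample per line (integer or float). An optional
#' leading comment `# fs=<rate>` overrides the default sampling rate; other
#' `#` lines are ignored.
#'
#' @param path file path.
#' @param fs default sampling rate if the file carries none.
#' @param measurement_id,subject_id identifiers; default to the file stem.
#' @return A [ppg_record()].
#' @export
read_ppg <- function(path, fs = 50, measurement_id = NULL, subject_id = NULL) {
  lines <- readr::read_lines(path)
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("fs\\s*=\\s*[0-9.]+", hdr))
  if (length(m)) fs <- as.numeric(sub(".*=\\s*", "", m[[1]]))
  vals <- suppressWarnings(as.numeric(grep("^#", lines, value = TRUE, invert = TRUE)))
  vals <- vals[!is.na(vals)]
  stem <- sub("\\.[^.]*$", "", basename(path))
  ppg_record(vals, fs = fs,
             measurement_id = measurement_id %||% stem,
             subject_id = subject_id %||% stem)
}

#' Write a raw PPG text dump
#'
#' @param record a [ppg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ppg <- function(record, path) {
  readr::write_lines(
    c(sprintf("# fs=%g", record$fs), format(record$samples, trim = TRUE)),
    path)
  invisible(path)
}

#' Read a biometrics table
#'
#' Expects a delimited table with columns `subject_id`, `age`, `height_cm`,
#' `weight_kg` and optionally `bmi` (recomputed if absent).
#'
#' @param path file path (tab- or comma-delimited, with header).
#' @return tibble.
#' @export
read_biometrics <- function(path) {
  df <- readr::read_delim(path, show_col_types = FALSE)
  need <- c("subject_id", "age", "height_cm", "weight_kg")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste("biometrics table missing columns:", paste(miss, collapse = ", ")),
          class = "ppgbp_input_error")
  }
  if (!"bmi" %in% names(df)) {
    df$bmi <- df$weight_kg / (df$height_cm / 100)^2
  }
  as_tibble(df)
}

#' Read a reference blood-pressure table
#'
#' Expects columns `measurement_id`, `subject_id`, `ref_sbp`, `ref_dbp` and
#' optionally `cuff_discrepancy_flag` (TRUE when the two cuff readings
#' disagreed by more than 5 mmHg; such measurements are dropped before
#' modelling).
#'
#' @param path file path.
#' @param drop_discrepant drop rows flagged as cuff-discrepant.
#' @return tibble.
#' @export
read_reference <- function(path, drop_discrepant = TRUE) {
  df <- readr::read_delim(path, show_col_types = FALSE)
  need <- c("measurement_id", "subject_id", "ref_sbp", "ref_dbp")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste("reference table missing columns:", paste(miss, collapse = ", ")),
          class = "ppgbp_input_error")
  }
  if (!"cuff_discrepancy_flag" %in% names(df)) df$cuff_discrepancy_flag <- FALSE
  if (drop_discrepant) df <- df[!df$cuff_discrepancy_flag, ]
  as_tibble(df)
}

#' Write a delimited pipeline table
#'
#' Thin wrapper (tab-separated, header) used for QC reports, feature tables,
#' prediction tables and evaluation summaries.
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
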