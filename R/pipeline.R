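#' Run the full simulate -> QC -> features -> LOSO -> report pipeline
#'
#' Orchestrates the whole analysis on a synthetic cohort: simulation, beat
#' processing and quality control, feature extraction, leave-one-subject-out
#' validation, stratification and the evaluation report. With
#' `calibrate = TRUE`, each subject's measurements are additionally split
#' into calibration and held-out halves and median-error calibration is
#' applied.
#'
#' @param cfg a [synth_config()].
#' @param n_trees,min_leaf,half_width model parameters (see [bp_train()]).
#' @param calibrate also run the personal-calibration arm (needs at least 2
#'   measurements per subject).
#' @return list: `sim` (the simulated cohort), `qc` (QC report tibble),
#'   `beats` (selected-beat table), `loso` (stratified per-measurement
#'   predictions and errors), `report` ([bp_report()] output), and when
#'   requested `calibration` ([calibrate_loso()] output).
#' @export
run_pipeline <- function(cfg, n_trees = 100, min_leaf = 30, half_width = 0.5,
                         calibrate = FALSE) {
  sim <- simulate_cohort(cfg)
  fx <- extract_features(sim$measurements)
  loso <- loso_validate(fx$beats, sim$reference, n_trees = n_trees,
                        min_leaf = min_leaf, half_width = half_width,
                        seed = cfg$seed)
  loso <- dplyr::left_join(
    loso, fx$qc[, c("measurement_id", "mean_pi")], by = "measurement_id")
  loso <- stratify_measurements(loso, pi_col = "mean_pi")
  cal <- if (calibrate) calibrate_loso(loso) else NULL
  rep <- bp_report(loso, calibrated = if (!is.null(cal)) cal$heldout)
  list(sim = sim, qc = fx$qc, beats = fx$beats, loso = loso,
       report = rep, calibration = cal)
}

#' Write pipeline artifacts to a directory
#'
#' Emits the delimited tables a command-line run produces: QC report,
#' feature table (scalar features per selected beat), prediction table and
#' the evaluation report tables, plus the resolved configuration as YAML.
#'
#' @param result a [run_pipeline()] result.
#' @param cfg the [synth_config()] used.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_tsv(result$qc, file.path(out_dir, "qc_report.tsv"))
  feat <- result$beats[, c("measurement_id", "subject_id", "beat_idx",
                           "hr", "b_a", "c_a", "d_a", "e_a", "si", "bmi")]
  write_table_tsv(feat, file.path(out_dir, "feature_table.tsv"))
  pred_cols <- intersect(
    c("measurement_id", "subject_id", "fold", "ref_sbp", "ref_dbp",
      "pred_sbp", "pred_dbp", "err_sbp", "err_dbp", "age_group",
      "sbp_group", "pi_group"), names(result$loso))
  write_table_tsv(result$loso[, pred_cols],
                  file.path(out_dir, "predictions.tsv"))
  for (nm in names(result$report)) {
    write_table_tsv(result$report[[nm]],
                    file.path(out_dir, paste0("report_", nm, ".tsv")))
  }
  if (!is.null(result$calibration)) {
    write_table_tsv(result$calibration$factors,
                    file.path(out_dir, "calibration_factors.tsv"))
    held_cols <- intersect(
      c("measurement_id", "subject_id", "ref_sbp", "ref_dbp", "pred_sbp",
        "pred_dbp", "err_sbp", "err_dbp", "cal_sbp", "cal_dbp",
        "cal_err_sbp", "cal_err_dbp"), names(result$calibration$heldout))
    write_table_tsv(result$calibration$heldout[, held_cols],
                    file.path(out_dir, "calibrated_predictions.tsv"))
  }
  writeLines(yaml::as.yaml(unclass(cfg)), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Write a simulated cohort to disk in the device formats
#'
#' One raw PPG text file per measurement plus biometrics, reference and
#' ground-truth tables — the same formats the CLI reads back.
#'
#' @param sim a [simulate_cohort()] result.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(sim, out_dir) {
  dir.create(file.path(out_dir, "ppg"), recursive = TRUE, showWarnings = FALSE)
  for (m in sim$measurements) {
    write_ppg(m$record, file.path(out_dir, "ppg",
                                  paste0(m$record$measurement_id, ".txt")))
  }
  bio <- sim$cohort[, c("subject_id", "age", "height_cm", "weight_kg", "bmi")]
  write_table_tsv(bio, file.path(out_dir, "biometrics.tsv"))
  ref <- dplyr::bind_rows(purrr::map(sim$measurements, "ref"))
  write_table_tsv(ref[, c("measurement_id", "subject_id", "ref_sbp",
                          "ref_dbp", "cuff_discrepancy_flag")],
                  file.path(out_dir, "reference.tsv"))
  truth <- dplyr::bind_rows(purrr::map(sim$measurements, function(m) {
    dplyr::mutate(m$truth, measurement_id = m$record$measurement_id,
                  .before = 1)
  }))
  write_table_tsv(truth, file.path(out_dir, "ground_truth.tsv"))
  invisible(out_dir)
}

#' Load measurements from disk (raw PPG + biometrics + reference)
#'
#' Reads the formats written by [write_cohort()] / produced by the
#' recording device: a directory of one-sample-per-line PPG text files and
#' the two delimited tables.
#'
#' @param ppg_dir directory of `<measurement_id>.txt` PPG dumps.
#' @param biometrics_path,reference_path table paths.
#' @param fs default sampling rate for files without an `# fs=` header.
#' @return list of measurement objects (layout of
#'   [simulate_cohort()]`$measurements`).
#' @export
load_measurements <- function(ppg_dir, biometrics_path, reference_path,
                              fs = 50) {
  bio <- read_biometrics(biometrics_path)
  ref <- read_reference(reference_path)
  ref <- dplyr::inner_join(ref, bio, by = "subject_id")
  purrr::map(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    path <- file.path(ppg_dir, paste0(r$measurement_id, ".txt"))
    if (!file.exists(path)) {
      abort(paste("missing PPG file:", path), class = "ppgbp_input_error")
    }
    rec <- read_ppg(path, fs = fs, measurement_id = r$measurement_id,
                    subject_id = r$subject_id)
    list(record = rec, ref = r)
  })
}
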