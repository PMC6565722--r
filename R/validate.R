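#' Leave-one-subject-out validation
#'
#' For each subject, all of that subject's measurements are removed from
#' the training set; the SVD bases and both ensembles are refitted on the
#' remainder; the held-out measurements are predicted. Fold hygiene is a
#' hard assertion: a fold aborts if any test subject row reaches the
#' training matrix.
#'
#' @param beats selected-beat tibble from [extract_features()].
#' @param reference tibble with `measurement_id`, `subject_id`, `ref_sbp`,
#'   `ref_dbp` (plus any columns to carry through, e.g. `age`, `pi_level`).
#' @param n_trees,min_leaf,mtry,half_width passed to [bp_train()].
#' @param seed master seed; each fold derives its own sub-seed.
#' @return tibble, one row per accepted measurement: reference columns plus
#'   `pred_sbp`, `pred_dbp`, `err_sbp`, `err_dbp` (prediction minus
#'   reference) and `fold`.
#' @export
loso_validate <- function(beats, reference, n_trees = 100, min_leaf = 30,
                          mtry = NULL, half_width = 0.5, seed = 1L) {
  subjects <- sort(unique(beats$subject_id))
  if (length(subjects) < 3) {
    abort("leave-one-subject-out needs at least 3 subjects",
          class = "ppgbp_input_error")
  }
  preds <- purrr::map(subjects, function(sid) {
    train_beats <- beats[beats$subject_id != sid, ]
    test_beats <- beats[beats$subject_id == sid, ]
    if (!nrow(test_beats)) return(NULL)
    stopifnot(length(intersect(train_beats$subject_id,
                               test_beats$subject_id)) == 0)
    est <- bp_train(train_beats,
                    reference[reference$subject_id != sid, ],
                    n_trees = n_trees, min_leaf = min_leaf, mtry = mtry,
                    seed = derive_seed(seed, "fold", sid),
                    half_width = half_width)
    p <- predict(est, test_beats)
    p$fold <- sid
    p
  })
  out <- dplyr::bind_rows(preds)
  out <- dplyr::inner_join(out, reference,
                           by = c("measurement_id", "subject_id"))
  out$err_sbp <- out$pred_sbp - out$ref_sbp
  out$err_dbp <- out$pred_dbp - out$ref_dbp
  out
}

#' Personal calibration factor from prior errors
#'
#' The median of a subject's previous fitting errors (prediction minus
#' reference), computed per pressure type.
#'
#' @param prior_errors numeric vector of prior errors, mmHg (at least 1).
#' @return the median, mmHg.
#' @export
#' @examples
#' calibration_factor(c(5, 3, 7))  # 5
calibration_factor <- function(prior_errors) {
  if (!length(prior_errors) || all(is.na(prior_errors))) {
    abort("no prior measurements to calibrate from", class = "ppgbp_input_error")
  }
  median(prior_errors, na.rm = TRUE)
}

#' Apply a personal calibration factor
#'
#' Calibration subtracts the subject's factor from the calibration-free
#' estimate.
#'
#' @param pred predicted pressure(s), mmHg.
#' @param factor calibration factor from [calibration_factor()], mmHg.
#' @return calibrated prediction(s).
#' @export
apply_calibration <- function(pred, factor) {
  stopifnot(length(factor) == 1, is.finite(factor))
  pred - factor
}

#' Calibrate leave-one-subject-out predictions per subject
#'
#' Splits each subject's measurements (in measurement order) into a
#' calibration set (the first `n_cal`) and a held-out set; computes the
#' per-subject calibration factor as the median error over the calibration
#' set and subtracts it from the held-out predictions.
#'
#' @param loso tibble from [loso_validate()].
#' @param n_cal number of prior measurements per subject used for the
#'   factor (default: half, at least 1).
#' @return list with `heldout` (held-out rows with `cal_sbp`, `cal_dbp`,
#'   `cal_err_sbp`, `cal_err_dbp` added) and `factors` (per-subject tibble).
#' @export
calibrate_loso <- function(loso, n_cal = NULL) {
  loso <- loso[order(loso$subject_id, loso$measurement_id), ]
  split <- loso %>%
    dplyr::group_by(.data$subject_id) %>%
    dplyr::mutate(.rank = dplyr::row_number(), .n = dplyr::n()) %>%
    dplyr::ungroup()
  nc <- function(n) if (is.null(n_cal)) pmax(1L, n %/% 2L) else n_cal
  split$.is_cal <- split$.rank <= nc(split$.n)
  cal <- split[split$.is_cal, ]
  held <- split[!split$.is_cal, ]
  factors <- cal %>%
    dplyr::group_by(.data$subject_id) %>%
    dplyr::summarise(sbp_factor = calibration_factor(.data$err_sbp),
                     dbp_factor = calibration_factor(.data$err_dbp),
                     n_prior = dplyr::n(), .groups = "drop")
  held <- dplyr::inner_join(held, factors, by = "subject_id")
  held$cal_sbp <- held$pred_sbp - held$sbp_factor
  held$cal_dbp <- held$pred_dbp - held$dbp_factor
  held$cal_err_sbp <- held$cal_sbp - held$ref_sbp
  held$cal_err_dbp <- held$cal_dbp - held$ref_dbp
  held$.rank <- held$.n <- held$.is_cal <- NULL
  list(heldout = held, factors = factors,
       calibration = cal[, setdiff(names(cal), c(".rank", ".n", ".is_cal"))])
}
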