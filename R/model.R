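#' Perturb a reference pressure into per-beat training targets
#'
#' Each measurement contributes 30 beat rows but only one cuff reference;
#' targets are the reference plus independent uniform draws on
#' [-0.5, +0.5] mmHg, so a reference of 130 yields 30 targets in
#' [129.5, 130.5].
#'
#' @param ref_bp reference pressure, mmHg.
#' @param n number of targets (default 30).
#' @param seed integer seed (draws are reproducible given it).
#' @param half_width perturbation half-width, mmHg (default 0.5).
#' @return numeric vector of length `n`.
#' @export
#' @examples
#' range(perturb_targets(130, 30, seed = 1))  # within [129.5, 130.5]
perturb_targets <- function(ref_bp, n = 30, seed = 1L, half_width = 0.5) {
  stopifnot(n >= 1)
  withr::with_seed(seed, runif(n, ref_bp - half_width, ref_bp + half_width))
}

# canonical row order so bootstrap draws do not depend on input ordering
canonical_order <- function(df) {
  df[order(df$subject_id, df$measurement_id, df$beat_idx), ]
}

# project shape list-columns onto fold bases -> numeric feature matrix
feature_matrix <- function(beats, ppg_basis, sdptg_basis) {
  p <- t(vapply(beats$ppg_shape, project_beat, numeric(4), basis = ppg_basis))
  s <- t(vapply(beats$sdptg_shape, project_beat, numeric(8), basis = sdptg_basis))
  m <- cbind(p, s, beats$hr, beats$b_a, beats$c_a, beats$d_a, beats$e_a,
             beats$si, beats$bmi)
  colnames(m) <- feature_names()
  m
}

#' Train the blood-pressure estimator
#'
#' Fits the two SVD waveform bases (4 PPG components, 8 SDPTG components)
#' on the training beats, projects them, perturbs each measurement's
#' reference SBP and DBP into per-beat targets, and fits two
#' bootstrap-aggregated regression-tree ensembles (minimum leaf size 30)
#' — one for SBP, one for DBP.
#'
#' @param beats selected-beat tibble from [extract_features()] (30 rows per
#'   accepted measurement, with `ppg_shape`/`sdptg_shape` list-columns).
#' @param reference tibble with `measurement_id`, `ref_sbp`, `ref_dbp`.
#' @param n_trees ensemble size (default 100).
#' @param min_leaf minimum terminal-node size (default 30).
#' @param mtry predictors sampled per split; default one third of the 19
#'   features, the regression default of the ensemble implementation the
#'   method was developed with. Set to 19 for pure bagging.
#' @param seed master seed for target perturbation and bootstrap draws.
#' @param half_width target perturbation half-width, mmHg.
#' @return object of class `"bp_estimator"`.
#' @export
bp_train <- function(beats, reference, n_trees = 100, min_leaf = 30,
                     mtry = NULL, seed = 1L, half_width = 0.5) {
  stopifnot(nrow(beats) > 0)
  beats <- canonical_order(beats)
  ref <- reference[match(unique(beats$measurement_id),
                         reference$measurement_id), ]
  if (anyNA(ref$measurement_id)) {
    abort("reference pressures missing for some measurements",
          class = "ppgbp_input_error")
  }
  if (dplyr::n_distinct(beats$measurement_id) < 2) {
    abort("need at least 2 measurements to train", class = "ppgbp_input_error")
  }
  ppg_basis <- fit_waveform_basis(beats$ppg_shape, 4)
  sdptg_basis <- fit_waveform_basis(beats$sdptg_shape, 8)
  x <- feature_matrix(beats, ppg_basis, sdptg_basis)

  targets <- purrr::map(c(sbp = "ref_sbp", dbp = "ref_dbp"), function(col) {
    unlist(purrr::map2(ref$measurement_id, ref[[col]], function(mid, bp) {
      nb <- sum(beats$measurement_id == mid)
      perturb_targets(bp, nb, seed = derive_seed(seed, "perturb", col, mid),
                      half_width = half_width)
    }))
  })
  if (sd(targets$sbp) == 0 || sd(targets$dbp) == 0) {
    warn("degenerate constant targets: ensembles will predict a constant")
  }

  fit_one <- function(y, label) {
    df <- as.data.frame(x)
    df$.target <- y
    ranger::ranger(
      dependent.variable.name = ".target", data = df,
      num.trees = n_trees, mtry = mtry %||% max(1L, ncol(x) %/% 3L),
      replace = TRUE,
      min.node.size = min_leaf, num.threads = 1,
      seed = derive_seed(seed, "bag", label)
    )
  }
  sbp_fit <- fit_one(targets$sbp, "sbp")
  dbp_fit <- fit_one(targets$dbp, "dbp")
  structure(list(
    sbp_fit = sbp_fit, dbp_fit = dbp_fit,
    ppg_basis = ppg_basis, sdptg_basis = sdptg_basis,
    n_trees = n_trees, min_leaf = min_leaf, seed = seed,
    half_width = half_width,
    n_measurements = dplyr::n_distinct(beats$measurement_id),
    n_beats = nrow(beats),
    train_r2 = c(sbp = sbp_fit$r.squared, dbp = dbp_fit$r.squared)
  ), class = "bp_estimator")
}

#' @export
print.bp_estimator <- function(x, ...) {
  cat(sprintf(paste0("<bp_estimator: %d trees, min leaf %d, trained on %d ",
                     "beats / %d measurements>\n"),
              x$n_trees, x$min_leaf, x$n_beats, x$n_measurements))
  invisible(x)
}

#' Predict blood pressure for measurements
#'
#' Projects each selected beat onto the training-fold bases, runs both
#' ensembles per beat, and aggregates to one value per measurement as the
#' median of the per-beat predictions.
#'
#' @param object a [bp_train()] estimator.
#' @param beats selected-beat tibble (layout of [extract_features()]).
#' @param per_beat also return per-beat predictions.
#' @param ... unused.
#' @return tibble with `measurement_id`, `subject_id`, `pred_sbp`,
#'   `pred_dbp` (and a `beat_preds` list-column when `per_beat = TRUE`).
#' @export
predict.bp_estimator <- function(object, beats, per_beat = FALSE, ...) {
  stopifnot(nrow(beats) > 0)
  beats <- canonical_order(beats)
  x <- feature_matrix(beats, object$ppg_basis, object$sdptg_basis)
  df <- as.data.frame(x)
  pb <- tibble(
    measurement_id = beats$measurement_id,
    subject_id = beats$subject_id,
    beat_idx = beats$beat_idx,
    sbp = predict(object$sbp_fit, df, num.threads = 1)$predictions,
    dbp = predict(object$dbp_fit, df, num.threads = 1)$predictions
  )
  agg <- pb %>%
    dplyr::group_by(.data$measurement_id, .data$subject_id) %>%
    dplyr::summarise(pred_sbp = median(.data$sbp),
                     pred_dbp = median(.data$dbp), .groups = "drop")
  if (per_beat) {
    agg$beat_preds <- purrr::map(agg$measurement_id,
                                 ~ pb[pb$measurement_id == .x, ])
  }
  agg
}

#' @rdname tidy
#' @param x a `bp_estimator`.
#' @param ... unused.
#' @export
tidy.bp_estimator <- function(x, ...) {
  tibble(
    pressure = c("sbp", "dbp"),
    n_trees = x$n_trees,
    min_leaf = x$min_leaf,
    train_r2 = as.numeric(x$train_r2)
  )
}

#' @rdname glance
#' @param x a `bp_estimator`.
#' @param ... unused.
#' @export
glance.bp_estimator <- function(x, ...) {
  tibble(
    n_measurements = x$n_measurements,
    n_beats = x$n_beats,
    n_trees = x$n_trees,
    min_leaf = x$min_leaf,
    train_r2_sbp = x$train_r2[["sbp"]],
    train_r2_dbp = x$train_r2[["dbp"]]
  )
}
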