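#' Names of the 19 model features, in canonical order
#' @export
feature_names <- function() {
  c(paste0("p", 1:4), paste0("s", 1:8), "hr",
    "b_a", "c_a", "d_a", "e_a", "si", "bmi")
}

#' Resample a beat to a fixed-length array
#'
#' Linear interpolation onto `n` equally spaced points over the beat's
#' duration; the first and last samples are preserved.
#'
#' @param y numeric beat samples (length at least 4).
#' @param n output length (default 32).
#' @return numeric vector of length `n`.
#' @export
resample_beat <- function(y, n = 32) {
  if (length(y) < 4) {
    abort("beat too short to resample", class = "ppgbp_input_error")
  }
  if (length(y) == n) return(as.numeric(y))
  approx(seq(0, 1, length.out = length(y)), y,
         xout = seq(0, 1, length.out = n))$y
}

#' Normalise a beat shape
#'
#' Default `"minmax"` shifts the minimum to 0 and scales the peak to 1, so
#' SVD coefficients encode shape rather than perfusion amplitude; `"none"`
#' leaves the samples untouched.
#'
#' @param y numeric vector.
#' @param method `"minmax"` or `"none"`.
#' @return numeric vector.
#' @export
normalize_shape <- function(y, method = c("minmax", "none")) {
  method <- match.arg(method)
  if (method == "none") return(y)
  rng <- max(y) - min(y)
  if (rng == 0) return(y - min(y))
  (y - min(y)) / rng
}

#' Measurement template: pointwise median shape
#'
#' @param shapes matrix (beats x points) or list of equal-length vectors.
#' @return numeric vector, the pointwise median across beats.
#' @export
build_template <- function(shapes) {
  if (is.list(shapes) && !length(shapes)) {
    abort("no beats for template", class = "ppgbp_input_error")
  }
  m <- if (is.list(shapes)) do.call(rbind, shapes) else as.matrix(shapes)
  if (nrow(m) < 1) abort("no beats for template", class = "ppgbp_input_error")
  apply(m, 2, median)
}

#' Select the beats most similar to the template
#'
#' The `k` beats with the smallest Euclidean distance to the template are
#' kept; ties are broken in favour of the earlier beat.
#'
#' @param shapes matrix (beats x points) or list of vectors.
#' @param template numeric vector from [build_template()].
#' @param k number of beats to keep (default 30).
#' @return integer indices (rows of `shapes`) of the selected beats, in
#'   ascending beat order.
#' @export
select_beats <- function(shapes, template, k = 30) {
  m <- if (is.list(shapes)) do.call(rbind, shapes) else as.matrix(shapes)
  if (nrow(m) < k) {
    abort(sprintf("insufficient cycles: %d < %d", nrow(m), k),
          class = "ppgbp_qc_error")
  }
  d <- sqrt(rowSums((m - matrix(template, nrow(m), length(template),
                                byrow = TRUE))^2))
  sort(order(d, seq_along(d))[seq_len(k)])
}

#' Fit an SVD waveform basis
#'
#' Shapes are centred by their mean and decomposed by singular value
#' decomposition; the first `n_components` right singular directions form
#' the basis. Four components are used for the PPG stream and eight for the
#' SDPTG stream; the fractions of variance they explain are recorded as
#' diagnostics, not enforced. Each component's sign is fixed so its
#' largest-magnitude element is positive.
#'
#' @param shapes matrix (beats x 32) or list of 32-vectors.
#' @param n_components number of components to keep.
#' @return object of class `"waveform_basis"`: `mean_shape`, `components`
#'   (32 x n), `explained_variance` (per kept component), `n_components`.
#' @export
fit_waveform_basis <- function(shapes, n_components) {
  m <- if (is.list(shapes)) do.call(rbind, shapes) else as.matrix(shapes)
  if (nrow(m) < n_components + 1) {
    abort("too few beats to fit basis", class = "ppgbp_input_error")
  }
  mu <- colMeans(m)
  mc <- sweep(m, 2, mu)
  sv <- svd(mc, nu = 0, nv = n_components)
  if (sum(sv$d > max(dim(mc)) * .Machine$double.eps * sv$d[1]) < n_components) {
    abort(sprintf("training shapes have rank below %d components", n_components),
          class = "ppgbp_input_error")
  }
  v <- sv$v
  for (j in seq_len(ncol(v))) {
    if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  }
  structure(list(
    mean_shape = mu,
    components = v,
    explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
    n_components = n_components
  ), class = "waveform_basis")
}

#' @export
print.waveform_basis <- function(x, ...) {
  cat(sprintf("<waveform_basis: %d components, %.1f%% variance>\n",
              x$n_components, 100 * sum(x$explained_variance)))
  invisible(x)
}

#' Project a shape onto a fitted waveform basis
#'
#' @param shape numeric vector (same length as the basis mean).
#' @param basis a [fit_waveform_basis()] object.
#' @return numeric coefficient vector of length `n_components`.
#' @export
project_beat <- function(shape, basis) {
  stopifnot(inherits(basis, "waveform_basis"),
            length(shape) == length(basis$mean_shape))
  as.numeric(crossprod(basis$components, shape - basis$mean_shape))
}

#' Takazawa amplitude ratios of the SDPTG waves
#'
#' @param sdptg list from [compute_sdptg()].
#' @return named numeric `c(b_a, c_a, d_a, e_a)` of signed ratios.
#' @export
#' @examples
#' sdptg_ratios(list(a_amp = 2, b_amp = -1, c_amp = 0.4, d_amp = -0.2,
#'                   e_amp = 0.1, flag = NA))
sdptg_ratios <- function(sdptg) {
  if (!is.na(sdptg$flag) && sdptg$flag == "sdptg_incomplete") {
    abort("SDPTG incomplete: no ratios", class = "ppgbp_qc_error")
  }
  if (is.na(sdptg$a_amp) || sdptg$a_amp == 0) {
    abort("a-wave amplitude is zero", class = "ppgbp_qc_error")
  }
  c(b_a = sdptg$b_amp, c_a = sdptg$c_amp,
    d_a = sdptg$d_amp, e_a = sdptg$e_amp) / sdptg$a_amp
}

#' Assemble the 19-element feature vector
#'
#' Fixed order: P1..P4 (PPG shape), S1..S8 (SDPTG shape), heart rate,
#' b/a, c/a, d/a, e/a, stiffness index, BMI.
#'
#' @param p 4 PPG-shape coefficients.
#' @param s 8 SDPTG-shape coefficients.
#' @param hr heart rate, bpm.
#' @param ratios named vector from [sdptg_ratios()].
#' @param si stiffness index, m/s.
#' @param bmi body-mass index, kg/m2.
#' @return named numeric vector of length 19, or an error naming the
#'   missing part.
#' @export
assemble_features <- function(p, s, hr, ratios, si, bmi) {
  v <- c(p, s, hr, ratios[["b_a"]], ratios[["c_a"]], ratios[["d_a"]],
         ratios[["e_a"]], si, bmi)
  if (length(v) != 19 || any(!is.finite(v))) {
    abort("feature vector incomplete or non-finite", class = "ppgbp_qc_error")
  }
  setNames(v, feature_names())
}

#' Process one measurement into QC results and selected beat features
#'
#' Runs the full per-measurement chain: beat segmentation and annotation,
#' hemodynamic quality features, abnormal-beat flagging, SDPTG noise test,
#' 32-point resampling with min-max shape normalisation of both the PPG and
#' SDPTG streams, median template, and top-30 selection by template
#' similarity. Shape coefficients are NOT computed here: SVD bases belong
#' to the training fold and are fitted later.
#'
#' @param record a [ppg_record()].
#' @param height_cm,bmi subject biometrics.
#' @param n_points resampling length (default 32).
#' @param n_select beats to select (default 30).
#' @param normalize shape normalisation, `"minmax"` or `"none"`.
#' @return list with `qc` (one-row tibble incl. `accepted`), `beats` (full
#'   annotated beat tibble) and `selected` (tibble of the selected beats:
#'   `beat_idx`, `ppg_shape`, `sdptg_shape` list-columns, `hr`, `b_a`,
#'   `c_a`, `d_a`, `e_a`, `si`, `bmi`; `NULL` when the measurement is
#'   rejected).
#' @export
process_measurement <- function(record, height_cm, bmi, n_points = 32,
                                n_select = 30, normalize = "minmax") {
  beats <- analyze_beats(record)
  if (nrow(beats) < 5) {
    abort("fewer than 5 beats detected", class = "ppgbp_qc_error")
  }
  q <- beat_quality(beats, height_cm, record$fs)
  q <- flag_abnormal_beats(q)
  good <- q[!q$abnormal & !q$noise_fail, ]
  qc <- qc_measurement(q, n_selected_good = nrow(good))
  qc$measurement_id <- record$measurement_id
  qc$subject_id <- record$subject_id
  qc <- qc[, c("measurement_id", "subject_id", setdiff(names(qc),
               c("measurement_id", "subject_id")))]
  if (!qc$accepted) {
    return(list(qc = qc, beats = q, selected = NULL))
  }
  ppg_shapes <- purrr::map(good$samples,
                           ~ normalize_shape(resample_beat(.x, n_points), normalize))
  sdptg_shapes <- purrr::map(good$sdptg,
                             ~ normalize_shape(resample_beat(.x$samples, n_points), normalize))
  template <- build_template(ppg_shapes)
  sel <- select_beats(ppg_shapes, template, k = n_select)
  picked <- good[sel, ]
  tibble(
    measurement_id = record$measurement_id,
    subject_id = record$subject_id,
    beat_idx = picked$beat_idx,
    ppg_shape = ppg_shapes[sel],
    sdptg_shape = sdptg_shapes[sel],
    hr = picked$hr,
    b_a = purrr::map_dbl(picked$sdptg, ~ .x$b_amp / .x$a_amp),
    c_a = purrr::map_dbl(picked$sdptg, ~ .x$c_amp / .x$a_amp),
    d_a = purrr::map_dbl(picked$sdptg, ~ .x$d_amp / .x$a_amp),
    e_a = purrr::map_dbl(picked$sdptg, ~ .x$e_amp / .x$a_amp),
    si = picked$si,
    bmi = bmi
  ) -> selected
  list(qc = qc, beats = q, selected = selected)
}

#' Extract per-beat features for a set of measurements
#'
#' Applies [process_measurement()] to every measurement and binds the
#' accepted ones. Returns both the QC report and the stacked selected-beat
#' table ready for fold-wise basis fitting and model training.
#'
#' @param measurements list of elements each holding `record` and a `ref`
#'   row with `height_cm` and `bmi` (the layout [simulate_cohort()]
#'   produces, or built from files by the CLI).
#' @param ... passed to [process_measurement()].
#' @return list with `qc` (tibble, one row per measurement) and `beats`
#'   (tibble, 30 rows per accepted measurement).
#' @export
extract_features <- function(measurements, ...) {
  res <- purrr::map(measurements, function(m) {
    out <- tryCatch(
      process_measurement(m$record, m$ref$height_cm, m$ref$bmi, ...),
      ppgbp_qc_error = function(e) NULL,
      ppgbp_signal_error = function(e) NULL
    )
    if (is.null(out)) {
      return(list(qc = tibble(measurement_id = m$record$measurement_id,
                              subject_id = m$record$subject_id,
                              n_beats = NA_integer_, n_abnormal = NA_integer_,
                              abnormal_fraction = NA_real_, n_good = 0L,
                              mean_pi = NA_real_, accepted = FALSE,
                              reject_reasons = "processing failed"),
                  selected = NULL))
    }
    out
  })
  list(
    qc = dplyr::bind_rows(purrr::map(res, "qc")),
    beats = dplyr::bind_rows(purrr::compact(purrr::map(res, "selected")))
  )
}

#' Write a waveform basis to a structured text file
#'
#' YAML with the mean shape, the components (column-wise) and metadata;
#' readable back with [read_waveform_basis()].
#'
#' @param basis a [fit_waveform_basis()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveform_basis <- function(basis, path) {
  stopifnot(inherits(basis, "waveform_basis"))
  obj <- list(
    n_components = basis$n_components,
    n_points = length(basis$mean_shape),
    mean_shape = as.numeric(basis$mean_shape),
    components = lapply(seq_len(ncol(basis$components)),
                        function(j) as.numeric(basis$components[, j])),
    explained_variance = as.numeric(basis$explained_variance)
  )
  writeLines(yaml::as.yaml(obj, precision = 17), path)
  invisible(path)
}

#' Read a waveform basis written by [write_waveform_basis()]
#'
#' @param path file path.
#' @return a `"waveform_basis"` object.
#' @export
read_waveform_basis <- function(path) {
  obj <- yaml::read_yaml(path)
  structure(list(
    mean_shape = as.numeric(obj$mean_shape),
    components = do.call(cbind, lapply(obj$components, as.numeric)),
    explained_variance = as.numeric(obj$explained_variance),
    n_components = obj$n_components
  ), class = "waveform_basis")
}
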