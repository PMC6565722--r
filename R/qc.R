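#' Perfusion index of a beat
#'
#' AC/DC: peak-to-trough amplitude over the mean of the beat samples. Raw
#' device counts are required — a non-positive baseline is an error.
#'
#' @param y numeric beat samples (raw counts).
#' @return dimensionless ratio.
#' @export
#' @examples
#' perfusion_index(c(99.5, 100, 100.5, 100))  # 0.01
perfusion_index <- function(y) {
  dc <- mean(y)
  if (!is.finite(dc) || dc <= 0) {
    abort("baseline invalid: non-positive DC", class = "ppgbp_qc_error")
  }
  (max(y) - min(y)) / dc
}

#' Stiffness index of a beat
#'
#' Subject height over the systolic-peak-to-dicrotic-notch time lapse,
#' an established large-artery stiffness surrogate.
#'
#' @param peak_idx,notch_idx beat-local fiducial indices.
#' @param height_cm subject height in cm (100–220).
#' @param fs sampling rate, Hz.
#' @return speed in m/s, or `NA` when the notch is missing.
#' @export
#' @examples
#' stiff_index(10, 10 + 0.25 * 50, 170, 50)  # 6.8 m/s
stiff_index <- function(peak_idx, notch_idx, height_cm, fs) {
  assert_scalar_num(height_cm, "height_cm", 100, 220)
  if (is.na(notch_idx) || notch_idx <= peak_idx) return(NA_real_)
  (height_cm / 100) / ((notch_idx - peak_idx) / fs)
}

#' Heart rate implied by one beat
#'
#' @param duration_s beat duration, seconds.
#' @return bpm.
#' @export
beat_heart_rate <- function(duration_s) {
  stopifnot(duration_s > 0)
  60 / duration_s
}

#' Areas under the beat waveform
#'
#' Trapezoidal areas of the baseline-subtracted beat (samples minus beat
#' minimum) from foot to dicrotic notch (`area1`) and from notch to beat
#' end (`area2`), scaled to sample-unit seconds.
#'
#' @param y numeric beat samples.
#' @param notch_idx beat-local notch index.
#' @param fs sampling rate, Hz.
#' @return named numeric `c(area1, area2)`; `NA`s when the notch is missing.
#' @export
beat_areas <- function(y, notch_idx, fs) {
  if (is.na(notch_idx)) return(c(area1 = NA_real_, area2 = NA_real_))
  y0 <- y - min(y)
  c(area1 = trapz_area(y0[1:notch_idx], fs),
    area2 = trapz_area(y0[notch_idx:length(y0)], fs))
}

#' SDPTG diastolic-segment noise test
#'
#' The SDPTG over the segment from the dicrotic notch to the next foot
#' (beat end) should be quiet; the beat fails when the standard deviation
#' of that segment strictly exceeds 15% of |b|. A segment sitting exactly
#' at the threshold passes.
#'
#' @param sdptg SDPTG samples of the beat (from [compute_sdptg()]).
#' @param notch_idx beat-local notch index.
#' @param b_amp signed amplitude of the b wave.
#' @param frac threshold fraction of |b| (default 0.15).
#' @return `TRUE` (pass) or `FALSE` (fail); `NA` when not evaluable.
#' @export
sdptg_noise_test <- function(sdptg, notch_idx, b_amp, frac = 0.15) {
  if (is.na(notch_idx) || is.na(b_amp)) return(NA)
  seg <- sdptg[notch_idx:length(sdptg)]
  if (length(seg) < 3) return(NA)
  sd(seg) <= frac * abs(b_amp)
}

#' Per-beat hemodynamic quality features
#'
#' Computes perfusion index, stiffness index, heart rate and the two
#' waveform areas for every beat of [analyze_beats()] output, and runs the
#' SDPTG noise test.
#'
#' @param beats tibble from [analyze_beats()].
#' @param height_cm subject height, cm.
#' @param fs sampling rate, Hz.
#' @param noise_frac SDPTG noise threshold as fraction of |b|.
#' @return `beats` with columns `pi`, `si`, `hr`, `area1`, `area2`,
#'   `noise_fail` appended.
#' @export
beat_quality <- function(beats, height_cm, fs, noise_frac = 0.15) {
  q <- purrr::pmap(
    list(beats$samples, beats$peak_idx, beats$notch_idx, beats$duration_s,
         beats$sdptg, beats$flags),
    function(y, pk, nt, dur, sd2, fl) {
      notch_ok <- is.na(fl) || !grepl("notchless", fl)
      nt_use <- if (notch_ok) nt else NA_integer_
      ar <- beat_areas(y, nt_use, fs)
      pass <- sdptg_noise_test(sd2$samples, nt_use, sd2$b_amp, noise_frac)
      # sub-sample peak/notch positions so the stiffness index is not
      # quantized to the 20 ms sample grid
      pk_r <- refine_extremum(y, pk)
      nt_r <- if (is.na(nt_use)) NA_real_ else refine_extremum(y, nt_use)
      tibble(pi = perfusion_index(y),
             si = stiff_index(pk_r, nt_r, height_cm, fs),
             hr = beat_heart_rate(dur),
             area1 = ar[["area1"]], area2 = ar[["area2"]],
             noise_fail = isFALSE(pass))
    })
  dplyr::bind_cols(beats, dplyr::bind_rows(q))
}

#' Flag abnormal beats by robust per-feature outlier detection
#'
#' For each of the five hemodynamic features (pi, si, hr, area1, area2), a
#' beat is an outlier when its value deviates from the measurement median
#' by more than 3 scaled median absolute deviations (scale 1.4826). One
#' outlying feature suffices to label the beat abnormal; fiducial flags
#' (boundary peak, notchless, incomplete SDPTG) also force abnormality.
#'
#' @param quality tibble from [beat_quality()] (at least 5 beats).
#' @param k MAD multiplier (default 3).
#' @param rel_floor minimum outlier threshold as a fraction of the feature
#'   median (default 0.05). On very clean signals the robust scale collapses
#'   towards zero and percent-level physiological variation would be
#'   flagged; genuine artifacts (spikes, double beats, dropouts) move
#'   features by far more than 5%.
#' @return `quality` with logical `abnormal` and character `abnormal_reasons`
#'   columns appended.
#' @export
flag_abnormal_beats <- function(quality, k = 3, rel_floor = 0.05) {
  if (nrow(quality) < 5) {
    abort("fewer than 5 beats: measurement unusable", class = "ppgbp_qc_error")
  }
  feats <- c("pi", "si", "hr", "area1", "area2")
  out <- matrix(FALSE, nrow(quality), length(feats),
                dimnames = list(NULL, feats))
  for (f in feats) {
    v <- quality[[f]]
    med <- median(v, na.rm = TRUE)
    s <- robust_scale(v)  # scaled MAD (1.4826), IQR fallback
    thr <- max(k * s, rel_floor * abs(med))
    out[, f] <- !is.na(v) & abs(v - med) > thr
    out[is.na(v), f] <- TRUE   # missing feature (e.g. no notch) is abnormal
  }
  reasons <- apply(out, 1, function(r) {
    fl <- feats[r]
    if (length(fl)) paste(fl, collapse = ",") else NA_character_
  })
  fid <- !is.na(quality$flags)
  quality$abnormal <- rowSums(out) > 0 | fid
  quality$abnormal_reasons <- dplyr::case_when(
    fid & !is.na(reasons) ~ paste(quality$flags, reasons, sep = ","),
    fid ~ quality$flags,
    TRUE ~ reasons
  )
  quality
}

#' Measurement-level accept/reject decision
#'
#' A measurement is excluded when the fraction of abnormal beats strictly
#' exceeds 20%, or when fewer than 30 good-quality cardiac cycles survive
#' all beat filters. Exactly 20% abnormal is kept.
#'
#' @param quality tibble from [flag_abnormal_beats()].
#' @param n_selected_good number of beats surviving all filters (abnormal,
#'   noise test, fiducial completeness); defaults to the count implied by
#'   `quality`.
#' @param max_abnormal_frac rejection threshold on the abnormal fraction.
#' @param min_cycles minimum good cycles required.
#' @return one-row tibble: `n_beats`, `n_abnormal`, `abnormal_fraction`,
#'   `n_good`, `mean_pi`, `accepted`, `reject_reasons`.
#' @export
qc_measurement <- function(quality, n_selected_good = NULL,
                           max_abnormal_frac = 0.20, min_cycles = 30) {
  stopifnot(nrow(quality) > 0)
  n <- nrow(quality)
  n_ab <- sum(quality$abnormal)
  frac <- n_ab / n
  good <- !quality$abnormal & !quality$noise_fail
  n_good <- n_selected_good %||% sum(good)
  reasons <- c(
    if (frac > max_abnormal_frac) sprintf("abnormal>%d%%", round(100 * max_abnormal_frac)),
    if (n_good < min_cycles) sprintf("fewer than %d cycles", min_cycles)
  )
  tibble(
    n_beats = n, n_abnormal = n_ab, abnormal_fraction = frac,
    n_good = n_good,
    mean_pi = mean(quality$pi[good], na.rm = TRUE),
    accepted = length(reasons) == 0,
    reject_reasons = if (length(reasons)) paste(reasons, collapse = "; ")
                     else NA_character_
  )
}
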