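#' Detect pulse feet (beat onsets) in a raw PPG record
#'
#' The record is band-pass filtered (0.5–10 Hz, zero-phase Butterworth),
#' steep upstrokes are found as first-derivative maxima, and each foot is
#' the local minimum immediately preceding its upstroke. Inter-foot
#' intervals outside the physiological gate 0.3–2.0 s (30–200 bpm) are
#' invalid: feet that do not bound at least one valid interval are dropped.
#' Detection is invariant to positive rescaling and baseline shifts of the
#' input.
#'
#' @param record a [ppg_record()] of at least 10 s.
#' @return Strictly increasing integer sample indices of pulse onsets.
#' @export
detect_feet <- function(record) {
  stopifnot(inherits(record, "ppg_record"))
  x <- record$samples
  fs <- record$fs
  if (length(x) < 10 * fs) {
    abort("record shorter than 10 s", class = "ppgbp_input_error")
  }
  if (sd(x) == 0) {
    abort("no pulsatile activity: constant signal", class = "ppgbp_signal_error")
  }
  ny <- fs / 2
  bf <- signal::butter(2, c(0.5, min(10, 0.9 * ny)) / ny, type = "pass")
  xf <- as.numeric(signal::filtfilt(bf, x - mean(x)))
  d1 <- diff(xf)
  # threshold from the interior only: zero-phase filtering leaves edge
  # transients in the first/last second that would inflate a raw quantile
  core <- d1[seq.int(round(fs), length(d1) - round(fs))]
  pos <- core[core > 0]
  if (!length(pos)) {
    abort("no pulsatile activity: no upstrokes", class = "ppgbp_signal_error")
  }
  thr <- 0.4 * quantile(pos, 0.95, names = FALSE)
  cand <- local_extrema(d1, "max")
  cand <- cand[d1[cand] > thr]
  if (length(cand) < 2) {
    abort("no pulsatile activity: fewer than 2 upstrokes", class = "ppgbp_signal_error")
  }
  # enforce minimum separation between upstrokes, keeping the steeper one
  min_sep <- round(0.3 * fs)
  keep <- integer(0)
  for (i in cand[order(-d1[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  ups <- sort(keep)
  # walk back from each upstroke to the preceding local minimum
  eps <- 1e-4 * diff(range(xf))
  feet <- vapply(ups, function(i) {
    j <- i
    lim <- max(1L, i - as.integer(round(0.5 * fs)))
    while (j > lim && xf[j - 1] <= xf[j] + eps) j <- j - 1L
    j
  }, integer(1))
  feet <- sort(unique(feet))
  if (length(feet) < 2) {
    abort("no pulsatile activity: fewer than 2 feet", class = "ppgbp_signal_error")
  }
  iv <- diff(feet) / fs
  ok <- iv >= 0.3 & iv <= 2.0
  bounds_valid <- c(ok, FALSE) | c(FALSE, ok)
  feet <- feet[bounds_valid]
  if (length(feet) < 2) {
    abort("no pulsatile activity: no physiological beats", class = "ppgbp_signal_error")
  }
  feet
}

#' Segment a record into beats
#'
#' One beat per consecutive foot pair whose interval lies in the 0.3–2.0 s
#' gate. Beats are foot-to-foot and closed on both ends, so consecutive
#' beats share their boundary sample and each beat holds one complete
#' cardiac cycle.
#'
#' @param record a [ppg_record()].
#' @param feet indices from [detect_feet()].
#' @return tibble, one row per beat: `beat_idx`, `start_idx`, `end_idx`,
#'   `n`, `duration_s`, `samples` (list-column).
#' @export
segment_beats <- function(record, feet) {
  stopifnot(inherits(record, "ppg_record"), length(feet) >= 2)
  fs <- record$fs
  iv <- diff(feet) / fs
  ok <- which(iv >= 0.3 & iv <= 2.0)
  purrr::map_dfr(ok, function(i) {
    s <- feet[i]; e <- feet[i + 1]
    tibble(beat_idx = i, start_idx = s, end_idx = e,
           n = e - s + 1L, duration_s = (e - s) / fs,
           samples = list(record$samples[s:e]))
  })
}

#' Locate the systolic peak of a beat
#'
#' @param y numeric beat samples (foot-to-foot).
#' @return list with `idx` (global maximum within the first 60% of the
#'   beat) and `flag` (`"peak_boundary"` when the maximum sits on the
#'   search-window edge, marking the beat unusable).
#' @export
locate_systolic_peak <- function(y) {
  n <- length(y)
  w <- max(3L, as.integer(ceiling(0.6 * n)))
  i <- which.max(y[seq_len(w)])
  flag <- if (i == 1L || i == w) "peak_boundary" else NA_character_
  list(idx = i, flag = flag)
}

#' Locate the dicrotic notch of a beat
#'
#' Searches `(peak, 0.9 n]` for the most prominent local minimum (prominence
#' at least 1% of beat amplitude). Absent one, falls back to the inflection
#' where the smoothed second derivative crosses zero upward (flag
#' `"notch_inflection"`); absent that too, the point of smallest
#' second-derivative magnitude is returned with flag `"notchless"` — such
#' beats are excluded from stiffness-index and SDPTG noise evaluation.
#'
#' @param y numeric beat samples.
#' @param peak_idx systolic-peak index from [locate_systolic_peak()].
#' @param fs sampling rate, Hz.
#' @return list with `idx` and `flag`.
#' @export
locate_dicrotic_notch <- function(y, peak_idx, fs) {
  n <- length(y)
  hi <- as.integer(ceiling(0.9 * n))
  if (peak_idx + 2 > hi) return(list(idx = NA_integer_, flag = "notchless"))
  win <- (peak_idx + 1):hi
  amp <- diff(range(y))
  mins <- local_extrema(y, "min")
  mins <- mins[mins %in% win]
  if (length(mins)) {
    prom <- vapply(mins, function(i) {
      left <- max(y[peak_idx:i]) - y[i]
      right <- max(y[i:min(n, hi + 1)]) - y[i]
      min(left, right)
    }, numeric(1))
    good <- prom >= 0.01 * amp
    if (any(good)) {
      m <- mins[good]
      return(list(idx = m[which.max(prom[good])], flag = NA_character_))
    }
  }
  d2 <- sdptg_curve(y, fs)
  seg <- d2[win]
  up <- which(seg[-length(seg)] < 0 & seg[-1] >= 0)
  if (length(up)) {
    return(list(idx = win[up[1] + 1L], flag = "notch_inflection"))
  }
  list(idx = win[which.min(abs(seg))], flag = "notchless")
}

# central-difference gradient with one-sided ends (per-sample units)
cgrad <- function(x) {
  n <- length(x)
  if (n < 3) return(c(diff(x), diff(x)[length(diff(x))]))
  c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
}

# smoothed second time-derivative of a beat (counts/s^2): quadratic
# Savitzky-Golay smoothing before each differentiation; raw double
# differencing at 50 Hz is noise-dominated. Window of 7 samples (140 ms)
# keeps zero-noise fiducials within one sample while suppressing enough
# noise for the diastolic-segment quality test to be meaningful.
sdptg_curve <- function(y, fs, sg_window = 7) {
  if (length(y) < 8) abort("beat too short for SDPTG", class = "ppgbp_input_error")
  w <- min(sg_window, length(y) - (1 - length(y) %% 2))
  if (w %% 2 == 0) w <- w - 1
  sm <- as.numeric(signal::sgolayfilt(y, p = 2, n = w))
  d1 <- cgrad(sm) * fs
  d1 <- as.numeric(signal::sgolayfilt(d1, p = 2, n = w))
  cgrad(d1) * fs
}

#' Compute the second-derivative photoplethysmogram (SDPTG) of a beat
#'
#' The beat is smoothed (quadratic Savitzky–Golay, default 7-sample window)
#' before each of two differentiations. The five systolic waves a–e are located as the
#' alternating extrema following the global early-systolic maximum a:
#' b is the first local minimum after a, then c (max), d (min), e (max).
#'
#' @param y numeric beat samples (length at least 8).
#' @param fs sampling rate, Hz.
#' @param sg_window Savitzky-Golay smoothing window (odd, samples).
#' @param peak_idx systolic-peak index bounding the search for the a wave;
#'   defaults to the first 40% of the beat when the peak is unknown.
#' @return list with `samples` (the SDPTG, counts/s^2), indices
#'   `a_idx`..`e_idx`, signed amplitudes `a_amp`..`e_amp`, and `flag`
#'   (`"sdptg_incomplete"` when fewer than five alternating extrema exist,
#'   `"sdptg_morphology"` when a <= 0 or b >= 0).
#' @export
compute_sdptg <- function(y, fs, peak_idx = NULL, sg_window = 7) {
  d2 <- sdptg_curve(y, fs, sg_window = sg_window)
  n <- length(d2)
  # degenerate (affine) beats: the curvature is numerically zero and any
  # extrema are floating-point noise, not waves
  if (diff(range(d2)) <= 1e-9 * max(diff(range(y)), .Machine$double.eps) * fs^2) {
    return(list(samples = d2, a_idx = NA_integer_, b_idx = NA_integer_,
                c_idx = NA_integer_, d_idx = NA_integer_, e_idx = NA_integer_,
                a_amp = NA_real_, b_amp = NA_real_, c_amp = NA_real_,
                d_amp = NA_real_, e_amp = NA_real_, flag = "sdptg_incomplete"))
  }
  hi <- peak_idx %||% as.integer(ceiling(0.4 * n))
  # skip the first two samples: the one-sided gradient ends distort them
  aw <- seq.int(3L, min(n, max(4L, hi)))
  a_i <- aw[which.max(d2[aw])]
  ext_max <- local_extrema(d2, "max")
  ext_min <- local_extrema(d2, "min")
  nxt <- function(pool, after) {
    p <- pool[pool > after]
    if (length(p)) p[1] else NA_integer_
  }
  b_i <- nxt(ext_min, a_i)
  c_i <- nxt(ext_max, b_i %||% NA_integer_)
  d_i <- if (is.na(c_i)) NA_integer_ else nxt(ext_min, c_i)
  e_i <- if (is.na(d_i)) NA_integer_ else nxt(ext_max, d_i)
  idx <- c(a_i, b_i, c_i, d_i, e_i)
  flag <- NA_character_
  if (anyNA(idx)) {
    flag <- "sdptg_incomplete"
  } else if (!(d2[a_i] > 0 && d2[b_i] < 0)) {
    flag <- "sdptg_morphology"
  }
  amp <- function(i) if (is.na(i)) NA_real_ else d2[i]
  list(samples = d2,
       a_idx = a_i, b_idx = b_i, c_idx = c_i, d_idx = d_i, e_idx = e_i,
       a_amp = amp(a_i), b_amp = amp(b_i), c_amp = amp(c_i),
       d_amp = amp(d_i), e_amp = amp(e_i), flag = flag)
}

#' Segment and annotate all beats of a record
#'
#' Runs foot detection, beat segmentation, fiducial location and SDPTG
#' computation, collecting per-beat flags.
#'
#' @param record a [ppg_record()].
#' @return tibble, one row per beat, with fiducial indices (beat-local,
#'   1-based), SDPTG list-column and a `flags` character column
#'   (comma-separated reason codes, `NA` when clean).
#' @export
analyze_beats <- function(record) {
  feet <- detect_feet(record)
  beats <- segment_beats(record, feet)
  ann <- purrr::map(beats$samples, function(y) {
    pk <- locate_systolic_peak(y)
    nt <- if (is.na(pk$flag)) locate_dicrotic_notch(y, pk$idx, record$fs)
          else list(idx = NA_integer_, flag = NA_character_)
    sd2 <- compute_sdptg(y, record$fs, peak_idx = pk$idx)
    flags <- stats::na.omit(c(pk$flag, nt$flag, sd2$flag))
    list(peak_idx = pk$idx, notch_idx = nt$idx, sdptg = sd2,
         flags = if (length(flags)) paste(flags, collapse = ",") else NA_character_)
  })
  beats$peak_idx <- purrr::map_int(ann, "peak_idx")
  beats$notch_idx <- purrr::map_int(ann, ~ .x$notch_idx %||% NA_integer_)
  beats$sdptg <- purrr::map(ann, "sdptg")
  beats$flags <- purrr::map_chr(ann, "flags")
  beats
}
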