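# Fixtures built in code: simple waveforms with known structure.

# pulse train of identical two-Gaussian beats at a fixed rate
make_pulse_train <- function(bpm = 75, fs = 50, duration_s = 20,
                             dc = 1000, ac = 20, drift_per_beat = 0) {
  period <- 60 / bpm
  n_beat <- round(period * fs)
  u <- (seq_len(n_beat) - 1) / n_beat
  shape <- exp(-((u - 0.22) / 0.09)^2 / 2) + 0.35 * exp(-((u - 0.55) / 0.14)^2 / 2)
  shape <- (shape - min(shape)) / (max(shape) - min(shape))
  n_beats <- ceiling(duration_s * fs / n_beat)
  x <- rep(dc + ac * shape, n_beats)[seq_len(duration_s * fs)]
  x + drift_per_beat * ac * (seq_along(x) - 1) / n_beat
}

# one beat with a single Gaussian bump centred at a chosen sample
make_gaussian_beat <- function(n = 40, center = 12, width = 4, amp = 1,
                               base = 100) {
  i <- seq_len(n)
  base + amp * exp(-((i - center) / width)^2 / 2)
}

# beat with systolic and diastolic humps and a valley between them
make_two_hump_beat <- function(n = 40, c1 = 12, c2 = 30, w1 = 4, w2 = 5,
                               a2 = 0.55, base = 100, amp = 10) {
  i <- seq_len(n)
  base + amp * (exp(-((i - c1) / w1)^2 / 2) + a2 * exp(-((i - c2) / w2)^2 / 2))
}

# minimal per-beat quality table for testing the outlier rule directly
make_quality <- function(n = 40, pi = 0.02, si = 8, hr = 75, area1 = 10,
                         area2 = 6) {
  tibble::tibble(
    beat_idx = seq_len(n),
    pi = rep_len(pi, n), si = rep_len(si, n), hr = rep_len(hr, n),
    area1 = rep_len(area1, n), area2 = rep_len(area2, n),
    flags = NA_character_, noise_fail = FALSE
  )
}

# small synthetic selected-beat table in the layout extract_features() emits,
# with shapes lying in a known low-dimensional family
make_beat_table <- function(n_meas = 4, beats_per_meas = 10, seed = 1,
                            si_from_sbp = NULL, sbp = NULL) {
  withr::with_seed(seed, {
    rows <- list()
    k <- 0
    for (m in seq_len(n_meas)) {
      for (b in seq_len(beats_per_meas)) {
        k <- k + 1
        u <- seq(0, 1, length.out = 32)
        shp <- exp(-((u - 0.25) / (0.08 + 0.01 * m))^2 / 2) + rnorm(32, 0, 0.01)
        sdp <- cos(2 * pi * u * (1 + 0.1 * m)) + rnorm(32, 0, 0.01)
        si <- if (is.null(si_from_sbp)) 8 + 0.1 * m + rnorm(1, 0, 0.05)
              else si_from_sbp(sbp[m]) + rnorm(1, 0, 0.02)
        rows[[k]] <- tibble::tibble(
          measurement_id = sprintf("M%02d", m),
          subject_id = sprintf("S%02d", (m + 1) %/% 2),
          beat_idx = b,
          ppg_shape = list(shp), sdptg_shape = list(sdp),
          hr = 72 + rnorm(1, 0, 1), b_a = -0.8 + rnorm(1, 0, 0.02),
          c_a = 0.2 + rnorm(1, 0, 0.02), d_a = -0.15 + rnorm(1, 0, 0.02),
          e_a = 0.1 + rnorm(1, 0, 0.02), si = si, bmi = 22 + m
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}
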