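#' Configuration for the synthetic PPG cohort generator
#'
#' Builds the parameter list that [sample_cohort()] and
#' [generate_measurement()] consume. Defaults emulate the marginal
#' biometrics of a mixed community/in-hospital adult cohort (young arm
#' centred at 36 y, older arm at 69 y, BMI about 24 kg/m2, height about
#' 163 cm, systolic pressure 119 mmHg young / 131 mmHg older) and a
#' 50 Hz finger pulse-oximeter recording of 60 s per measurement.
#'
#' The latent model: each subject carries a true SBP/DBP; the waveform
#' morphology is driven by an "effective" pressure equal to the true value
#' plus a per-subject bias (device placement, physiology), minus a fixed
#' penalty when peripheral perfusion is poor (perfusion index < 0.01 —
#' weak pulses read low), plus small per-measurement jitter. The cuff
#' reference is the true value plus irreducible measurement noise
#' (`sigma0_sbp` mmHg). `sigma0_sbp` is therefore the noise floor no
#' morphology-based estimator can beat.
#'
#' @param n_subjects number of subjects.
#' @param measurements_per_subject recordings per subject.
#' @param duration_s recording length, seconds.
#' @param fs sampling rate, Hz.
#' @param seed master seed (mandatory); all randomness derives from it.
#' @param young_fraction fraction of subjects drawn from the young arm.
#' @param sigma0_sbp,sigma0_dbp irreducible cuff-reference noise, mmHg.
#' @param subject_bias_sd SD of the per-subject morphology-vs-cuff offset,
#'   mmHg. Raise it to emulate a cohort where personal calibration pays off.
#' @param within_meas_sd per-measurement morphology jitter, mmHg.
#' @param pi_penalty morphology underestimation applied when the subject's
#'   perfusion index is below 0.01, mmHg.
#' @param noise_sd additive waveform noise, as a fraction of the pulsatile
#'   (AC) amplitude.
#' @param low_pi_noise_mult multiplier on `noise_sd` for poorly perfused
#'   subjects (low perfusion also means low SNR).
#' @param drift_frac baseline drift amplitude as a fraction of AC.
#' @param hrv_sd fractional SD of beat-to-beat period variability.
#' @param notch_damping strength of dicrotic-notch damping with age
#'   (0 disables; 1 removes the diastolic lobe entirely by age 90).
#' @param dc_mean mean device-count level of the recording (DC).
#' @return A named list of generator parameters, class `"synth_config"`.
#' @export
#' @examples
#' cfg <- synth_config(n_subjects = 4, seed = 1)
synth_config <- function(n_subjects = 60,
                         measurements_per_subject = 2,
                         duration_s = 60,
                         fs = 50,
                         seed = NULL,
                         young_fraction = 0.40,
                         sigma0_sbp = 5,
                         sigma0_dbp = 3,
                         subject_bias_sd = 3,
                         within_meas_sd = 2,
                         pi_penalty = 15,
                         noise_sd = 0.01,
                         low_pi_noise_mult = 2,
                         drift_frac = 0.3,
                         hrv_sd = 0.02,
                         notch_damping = 0.3,
                         dc_mean = 10000) {
  if (is.null(seed)) abort("a master `seed` is mandatory", class = "ppgbp_config_error")
  assert_scalar_num(seed, "seed", 0, 2^31 - 2)
  assert_scalar_num(n_subjects, "n_subjects", 1)
  assert_scalar_num(duration_s, "duration_s", 1)
  assert_scalar_num(fs, "fs", 1)
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    measurements_per_subject = as.integer(measurements_per_subject),
    duration_s = duration_s, fs = fs, seed = as.integer(seed),
    young_fraction = young_fraction,
    # biometric marginals (mean, sd) per age arm
    age_young = c(36.0, 8.4), age_older = c(69.3, 11.6),
    height = c(163, 8), bmi = c(24.4, 3.8),
    sbp_young = c(118.7, 17.0), sbp_older = c(130.5, 18.6),
    dbp_young = c(76.2, 12.0), dbp_older = c(71.6, 12.2),
    hr = c(72, 9),
    # biometric couplings to pressure (mmHg per unit): adiposity and resting
    # heart rate both associate with higher pressure in adult cohorts
    bmi_sbp_slope = 1.2, bmi_dbp_slope = 0.8,
    hr_sbp_slope = 0.15, hr_dbp_slope = 0.10,
    pi_meanlog = log(0.012), pi_sdlog = 0.55,
    sigma0_sbp = sigma0_sbp, sigma0_dbp = sigma0_dbp,
    subject_bias_sd = subject_bias_sd, within_meas_sd = within_meas_sd,
    pi_penalty = pi_penalty,
    noise_sd = noise_sd, low_pi_noise_mult = low_pi_noise_mult,
    drift_frac = drift_frac, drift_period_s = 25,
    hrv_sd = hrv_sd, notch_damping = notch_damping, dc_mean = dc_mean,
    # morphology -> pressure coupling. Lobe timing is in absolute seconds
    # (pulse reflection timing does not scale with cycle length), so the
    # stiffness index h/deltaT tracks pressure rather than heart rate.
    t1 = 0.17,                # foot-to-systolic-peak time, s
    sL = 0.055,               # upstroke-side systolic width, s
    sR_0 = 0.050, sR_slope = -3.5e-4,  # decay-side width narrows with SBP:
                              # faster decay pulls the dicrotic notch earlier
                              # and deepens b relative to a (stiffer vessels)
    dT_0 = 0.31, dT_slope = -2.5e-3,   # peak-to-notch lapse shrinks with SBP
    s2 = 0.12,                # diastolic lobe width, s
    a2_0 = 0.32, a2_slope = 4.0e-3     # diastolic amplitude tracks DBP
  )
  structure(cfg, class = "synth_config")
}

# truncated-normal draws by rejection (bounds are loose physiological gates)
rtnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Draw a synthetic subject cohort
#'
#' Biometrics come from truncated normals matching the configured marginals;
#' systolic pressure is age-arm dependent (older subjects run higher). BMI,
#' height and weight are kept mutually consistent.
#'
#' @param cfg a [synth_config()] list.
#' @return A tibble with one row per subject: `subject_id`, `age`,
#'   `height_cm`, `weight_kg`, `bmi`, `true_sbp`, `true_dbp`, `pi_level`,
#'   `hr_mean`, plus the latent per-subject biases used downstream.
#' @export
sample_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_subjects
  withr::with_seed(derive_seed(cfg$seed, "cohort"), {
    young <- runif(n) < cfg$young_fraction
    age <- ifelse(young,
                  rtnorm(n, cfg$age_young[1], cfg$age_young[2], 18, 50),
                  rtnorm(n, cfg$age_older[1], cfg$age_older[2], 50.001, 95))
    height <- rtnorm(n, cfg$height[1], cfg$height[2], 140, 195)
    bmi <- rtnorm(n, cfg$bmi[1], cfg$bmi[2], 16, 40)
    sbp <- ifelse(young,
                  rtnorm(n, cfg$sbp_young[1], cfg$sbp_young[2], 90, 200),
                  rtnorm(n, cfg$sbp_older[1], cfg$sbp_older[2], 90, 200))
    dbp <- ifelse(young,
                  rtnorm(n, cfg$dbp_young[1], cfg$dbp_young[2], 40, 110),
                  rtnorm(n, cfg$dbp_older[1], cfg$dbp_older[2], 40, 110))
    hr_mean <- rtnorm(n, cfg$hr[1], cfg$hr[2], 50, 100)
    sbp <- sbp + cfg$bmi_sbp_slope * (bmi - cfg$bmi[1]) +
      cfg$hr_sbp_slope * (hr_mean - cfg$hr[1])
    dbp <- dbp + cfg$bmi_dbp_slope * (bmi - cfg$bmi[1]) +
      cfg$hr_dbp_slope * (hr_mean - cfg$hr[1])
    sbp <- pmin(pmax(sbp, 90), 200)
    dbp <- pmin(dbp, sbp - 25)
    dbp <- pmax(dbp, 40)
    tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      age = round(age, 1),
      height_cm = round(height, 1),
      bmi = round(bmi, 2),
      weight_kg = round(bmi * (height / 100)^2, 1),
      true_sbp = round(sbp, 1),
      true_dbp = round(dbp, 1),
      pi_level = exp(rnorm(n, cfg$pi_meanlog, cfg$pi_sdlog)),
      hr_mean = hr_mean,
      bias_sbp = rnorm(n, 0, cfg$subject_bias_sd),
      bias_dbp = rnorm(n, 0, 0.6 * cfg$subject_bias_sd)
    )
  })
}

# morphology parameters for one beat, converted to relative-phase units for
# the given cycle length; lobe timings/widths are physiologic absolutes (s)
beat_morphology <- function(sbp_eff, dbp_eff, age, period_s, cfg) {
  damp <- cfg$notch_damping * pmax(0, age - 60) / 30
  sR <- min(0.070, max(0.022, cfg$sR_0 + cfg$sR_slope * (sbp_eff - 120)))
  dT <- min(0.45, max(0.15, cfg$dT_0 + cfg$dT_slope * (sbp_eff - 120)))
  a2 <- min(0.60, max(0.12,
          (cfg$a2_0 + cfg$a2_slope * (dbp_eff - 75)) * (1 - min(0.9, damp))))
  list(
    u1 = cfg$t1 / period_s,
    swL = cfg$sL / period_s,
    swR = sR / period_s,
    u2 = min(0.78, (cfg$t1 + dT) / period_s),
    sw2 = cfg$s2 / period_s,
    a2 = a2
  )
}

# pulse shape and its exact derivatives on relative phase u: a two-sided
# (skewed) Gaussian systolic lobe plus a symmetric diastolic lobe. The
# systolic lobe is continuous with continuous slope at its centre; its
# curvature jumps there, which is what couples b/a to the decay-side width.
shape_eval <- function(u, m, deriv = 0) {
  g <- function(u, mu, s, d) {
    z <- (u - mu) / s
    e <- exp(-z^2 / 2)
    switch(as.character(d),
           "0" = e,
           "1" = -z / s * e,
           "2" = (z^2 - 1) / s^2 * e)
  }
  s1 <- ifelse(u < m$u1, m$swL, m$swR)
  g(u, m$u1, s1, deriv) + m$a2 * g(u, m$u2, m$sw2, deriv)
}

# analytic ground-truth fiducials for one beat of n samples (1-based indices)
beat_truth <- function(m, n) {
  fine <- seq(0, 1, length.out = 4001)
  s <- shape_eval(fine, m)
  d2 <- shape_eval(fine, m, deriv = 2)
  to_idx <- function(u) pmin(n, pmax(1, round(u * n) + 1L))
  pk_w <- fine <= 0.6
  peak_u <- fine[pk_w][which.max(s[pk_w])]
  # notch: local minimum of s between the two lobe centres
  win <- which(fine > m$u1 & fine < m$u2)
  mins <- win[local_extrema(s[win], "min")] + 0  # indices into fine via win
  mins <- intersect(win[1] - 1 + local_extrema(s[win], "min"), win)
  notch_u <- if (length(mins)) fine[mins[which.min(s[mins])]] else NA_real_
  # a-e waves: alternating extrema of the second derivative after its
  # early-systolic global maximum; "early systolic" ends at the waveform peak
  aw <- which(fine <= peak_u)
  a_i <- aw[which.max(d2[aw])]
  # persistence pruning: the curvature jump at the skewed lobe's centre
  # spawns adjacent micro-extrema on the fine grid that are not waves
  ext <- sort(c(local_extrema(d2, "max"), local_extrema(d2, "min")))
  tol <- 0.02 * diff(range(d2))
  repeat {
    if (length(ext) < 2) break
    gaps <- abs(diff(d2[ext]))
    k <- which.min(gaps)
    if (gaps[k] >= tol) break
    ext <- ext[-c(k, k + 1)]
  }
  ext_max <- ext[d2[ext] >= d2[pmax(ext - 1, 1)]]
  ext_min <- setdiff(ext, ext_max)
  nxt <- function(pool, after) { p <- pool[pool > after]; if (length(p)) p[1] else NA_integer_ }
  b_i <- nxt(ext_min, a_i); c_i <- nxt(ext_max, b_i)
  d_i <- nxt(ext_min, c_i); e_i <- nxt(ext_max, d_i)
  amp <- function(i) if (is.na(i)) NA_real_ else d2[i]
  list(
    peak_idx = to_idx(peak_u),
    notch_idx = if (is.na(notch_u)) NA_integer_ else to_idx(notch_u),
    a_idx = to_idx(fine[a_i]),
    b_idx = if (is.na(b_i)) NA_integer_ else to_idx(fine[b_i]),
    c_idx = if (is.na(c_i)) NA_integer_ else to_idx(fine[c_i]),
    d_idx = if (is.na(d_i)) NA_integer_ else to_idx(fine[d_i]),
    e_idx = if (is.na(e_i)) NA_integer_ else to_idx(fine[e_i]),
    ratios = c(b_a = amp(b_i), c_a = amp(c_i), d_a = amp(d_i), e_a = amp(e_i)) / d2[a_i]
  )
}

#' Generate one synthetic beat waveform with ground truth
#'
#' Evaluates the two-Gaussian-lobe pulse model for a given effective
#' pressure pair at the sampling grid of one cardiac cycle and returns the
#' samples (unit-normalised shape) together with analytically derived
#' fiducial indices (systolic peak, dicrotic notch, SDPTG a--e waves) and
#' the true SDPTG amplitude ratios.
#'
#' @param sbp_eff,dbp_eff effective pressures driving morphology, mmHg.
#' @param age subject age, years (drives notch damping).
#' @param period_s cycle length, seconds.
#' @param cfg a [synth_config()].
#' @return list with `shape` (length `round(period_s * fs)`, min 0 peak 1),
#'   `truth` (fiducial indices and ratios), `morph` (lobe parameters).
#' @export
generate_beat_waveform <- function(sbp_eff, dbp_eff, age, period_s, cfg) {
  m <- beat_morphology(sbp_eff, dbp_eff, age, period_s, cfg)
  n <- max(8L, as.integer(round(period_s * cfg$fs)))
  u <- (seq_len(n) - 1) / n
  s <- shape_eval(u, m)
  s <- (s - min(s)) / (max(s) - min(s))
  list(shape = s, truth = beat_truth(m, n), morph = m)
}

#' Generate one synthetic 50 Hz PPG measurement
#'
#' Concatenates beats with beat-to-beat period variability, applies the
#' subject's perfusion level (AC/DC), slow baseline drift and additive
#' Gaussian noise, and attaches the per-beat ground truth.
#'
#' @param profile one-row tibble from [sample_cohort()].
#' @param cfg a [synth_config()].
#' @param meas_idx measurement index within subject (drives the sub-seed).
#' @return list with `record` (a [ppg_record()]), `ref` (one-row tibble of
#'   reference/biometrics), and `truth` (per-beat tibble of start indices
#'   and fiducials).
#' @export
generate_measurement <- function(profile, cfg, meas_idx = 1L) {
  stopifnot(nrow(profile) == 1)
  sid <- profile$subject_id
  mid <- sprintf("%s_M%02d", sid, meas_idx)
  low_pi <- profile$pi_level < 0.01
  withr::with_seed(derive_seed(cfg$seed, "meas", sid, meas_idx), {
    sbp_eff <- profile$true_sbp + profile$bias_sbp +
      rnorm(1, 0, cfg$within_meas_sd) - if (low_pi) cfg$pi_penalty else 0
    dbp_eff <- profile$true_dbp + profile$bias_dbp +
      rnorm(1, 0, 0.6 * cfg$within_meas_sd) - if (low_pi) 0.5 * cfg$pi_penalty else 0
    ref_sbp <- profile$true_sbp + rnorm(1, 0, cfg$sigma0_sbp)
    ref_dbp <- profile$true_dbp + rnorm(1, 0, cfg$sigma0_dbp)
    hr_meas <- max(45, min(110, profile$hr_mean + rnorm(1, 0, 2)))
    period <- 60 / hr_meas
    n_total <- as.integer(round(cfg$duration_s * cfg$fs))

    samples <- numeric(0)
    truth <- list()
    start <- 1L
    bi <- 0L
    while (length(samples) < n_total) {
      bi <- bi + 1L
      p_b <- period * (1 + rnorm(1, 0, cfg$hrv_sd))
      bw <- generate_beat_waveform(sbp_eff, dbp_eff, profile$age, p_b, cfg)
      nb <- length(bw$shape)
      ac <- profile$pi_level * cfg$dc_mean
      dc0 <- cfg$dc_mean - ac * mean(bw$shape)
      beat <- dc0 + ac * bw$shape
      truth[[bi]] <- tibble(
        beat_idx = bi, start_idx = start, n = nb,
        peak_idx = bw$truth$peak_idx, notch_idx = bw$truth$notch_idx,
        a_idx = bw$truth$a_idx, b_idx = bw$truth$b_idx,
        c_idx = bw$truth$c_idx, d_idx = bw$truth$d_idx,
        e_idx = bw$truth$e_idx,
        b_a = bw$truth$ratios[["b_a"]], c_a = bw$truth$ratios[["c_a"]],
        d_a = bw$truth$ratios[["d_a"]], e_a = bw$truth$ratios[["e_a"]]
      )
      samples <- c(samples, beat)
      start <- start + nb
    }
    samples <- samples[seq_len(n_total)]
    ac <- profile$pi_level * cfg$dc_mean
    noise_sd <- cfg$noise_sd * ac * (if (low_pi) cfg$low_pi_noise_mult else 1)
    tt <- (seq_len(n_total) - 1) / cfg$fs
    drift <- cfg$drift_frac * ac *
      sin(2 * pi * tt / cfg$drift_period_s + runif(1, 0, 2 * pi))
    samples <- samples + drift + rnorm(n_total, 0, noise_sd)

    truth_df <- dplyr::bind_rows(truth)
    truth_df <- truth_df[truth_df$start_idx + truth_df$n - 1L <= n_total, ]
    list(
      record = ppg_record(samples, fs = cfg$fs,
                          measurement_id = mid, subject_id = sid),
      ref = tibble(
        measurement_id = mid, subject_id = sid,
        age = profile$age, height_cm = profile$height_cm,
        weight_kg = profile$weight_kg, bmi = profile$bmi,
        ref_sbp = round(ref_sbp, 1), ref_dbp = round(ref_dbp, 1),
        true_sbp = profile$true_sbp, true_dbp = profile$true_dbp,
        pi_level = profile$pi_level, sbp_eff = sbp_eff, dbp_eff = dbp_eff,
        cuff_discrepancy_flag = FALSE
      ),
      truth = truth_df
    )
  })
}

#' Simulate a full synthetic cohort
#'
#' @param cfg a [synth_config()].
#' @return list with `cohort` (subject tibble), `measurements` (list of
#'   [generate_measurement()] results) and `reference` (per-measurement
#'   biometrics + reference-pressure tibble).
#' @export
#' @examples
#' sim <- simulate_cohort(synth_config(n_subjects = 2, duration_s = 20, seed = 7))
#' nrow(sim$reference)
simulate_cohort <- function(cfg) {
  cohort <- sample_cohort(cfg)
  meas <- purrr::pmap(
    list(seq_len(nrow(cohort))),
    function(i) {
      purrr::map(seq_len(cfg$measurements_per_subject),
                 ~ generate_measurement(cohort[i, ], cfg, .x))
    }
  )
  meas <- purrr::flatten(meas)
  list(
    cohort = cohort,
    measurements = meas,
    reference = dplyr::bind_rows(purrr::map(meas, "ref"))
  )
}

#' Inject artifacts into a synthetic measurement
#'
#' Deterministic, seeded corruption used to exercise the quality-control
#' rules. Modes: `"spike"` adds a large transient inside each chosen beat;
#' `"dropout"` flattens the first half of each chosen beat; `"drift"` adds a
#' strong linear baseline ramp to the whole record; `"diastolic_noise"` adds
#' heavy noise to the dicrotic-notch-to-beat-end segment of chosen beats
#' (trips the SDPTG noise test).
#'
#' @param meas a [generate_measurement()] result.
#' @param mode corruption mode.
#' @param beat_fraction fraction of beats to corrupt (ignored for drift).
#' @param magnitude artifact size as a multiple of the AC amplitude.
#' @param seed integer seed for choosing beats/offsets.
#' @return `meas` with corrupted samples and a `manifest` of corrupted beat
#'   indices attached.
#' @export
corrupt_record <- function(meas, mode = c("spike", "dropout", "drift",
                                          "diastolic_noise"),
                           beat_fraction = 0.25, magnitude = 3, seed = 1L) {
  mode <- match.arg(mode)
  x <- meas$record$samples
  truth <- meas$truth
  ac <- diff(range(x))  # conservative AC proxy
  withr::with_seed(seed, {
    if (mode == "drift") {
      x <- x + seq(0, magnitude * ac, length.out = length(x))
      manifest <- truth$beat_idx
    } else {
      k <- max(1L, round(beat_fraction * nrow(truth)))
      pick <- sort(sample(truth$beat_idx, k))
      for (b in pick) {
        row <- truth[truth$beat_idx == b, ]
        lo <- row$start_idx
        hi <- row$start_idx + row$n - 1L
        if (mode == "spike") {
          at <- lo + sample.int(row$n - 2L, 1)
          x[at + 0:1] <- x[at + 0:1] + magnitude * ac
        } else if (mode == "dropout") {
          seg <- lo:(lo + row$n %/% 2)
          x[seg] <- x[seg[1]]
        } else { # diastolic_noise
          if (!is.na(row$notch_idx)) {
            seg <- (lo + row$notch_idx - 1L):hi
            x[seg] <- x[seg] + rnorm(length(seg), 0, magnitude * ac * 0.1)
          }
        }
      }
      manifest <- pick
    }
  })
  meas$record$samples <- x
  meas$manifest <- manifest
  meas
}
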