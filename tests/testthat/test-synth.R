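test_that("the generator is fully deterministic under the master seed", {
  cfg <- synth_config(n_subjects = 3, duration_s = 15, seed = 99)
  expect_identical(sample_cohort(cfg), sample_cohort(cfg))
  coh <- sample_cohort(cfg)
  m1 <- generate_measurement(coh[2, ], cfg, 1)
  m2 <- generate_measurement(coh[2, ], cfg, 1)
  expect_identical(m1$record$samples, m2$record$samples)
  expect_identical(m1$ref, m2$ref)
  # different measurement index -> different noise, same subject
  m3 <- generate_measurement(coh[2, ], cfg, 2)
  expect_false(identical(m1$record$samples, m3$record$samples))
})

test_that("cohort marginals match the configured arms", {
  cfg <- synth_config(n_subjects = 1000, seed = 5)
  coh <- sample_cohort(cfg)
  young <- coh$age <= 50
  expect_gt(sum(young), 300)
  se <- 8.4 / sqrt(sum(young))
  # truncation to [18, 50] shifts the young-arm mean by about -0.5 y
  expect_lt(abs(mean(coh$age[young]) - 36.0), 0.6 + 3 * se)
  expect_lt(abs(mean(coh$age[!young]) - 69.3), 1.2 + 3 * 11.6 / sqrt(sum(!young)))
  # biometric consistency
  expect_equal(coh$bmi, coh$weight_kg / (coh$height_cm / 100)^2, tolerance = 0.01)
  expect_true(all(coh$true_sbp >= 90 & coh$true_sbp <= 200))
  expect_true(all(coh$true_dbp >= 40 & coh$true_dbp < coh$true_sbp))
  # older arm runs higher systolic, as configured
  expect_gt(mean(coh$true_sbp[!young]), mean(coh$true_sbp[young]))
})

test_that("a 60 s measurement at the nominal rate has 3000 samples, ~75 beats", {
  cfg <- synth_config(n_subjects = 1, duration_s = 60, seed = 31, hrv_sd = 0)
  coh <- sample_cohort(cfg)
  coh$hr_mean <- 75
  m <- generate_measurement(coh[1, ], cfg, 1)
  expect_length(m$record$samples, 3000)
  expect_gte(nrow(m$truth), 72)
  expect_lte(nrow(m$truth), 76)
})

test_that("generated perfusion straddles the 0.01 threshold as configured", {
  cfg <- synth_config(n_subjects = 1, duration_s = 20, seed = 17,
                      noise_sd = 0, drift_frac = 0)
  coh <- sample_cohort(cfg)
  for (lvl in c(0.005, 0.02)) {
    coh$pi_level <- lvl
    m <- generate_measurement(coh[1, ], cfg, 1)
    beats <- segment_beats(m$record, detect_feet(m$record))
    pis <- vapply(beats$samples, perfusion_index, numeric(1))
    if (lvl < 0.01) expect_lt(median(pis), 0.01) else expect_gt(median(pis), 0.01)
    expect_equal(median(pis), lvl, tolerance = 0.15)
  }
})

test_that("clean generator output passes QC nearly everywhere", {
  cfg <- synth_config(n_subjects = 2, duration_s = 60, seed = 23,
                      noise_sd = 0, drift_frac = 0)
  coh <- sample_cohort(cfg)
  coh$pi_level <- pmax(coh$pi_level, 0.012)  # keep the clean-signal arm
  # mid-range rates: at high heart rate the late SDPTG waves legitimately
  # run off the cycle end and QC flags those beats even on clean signal
  coh$hr_mean <- c(66, 72)
  for (i in 1:2) {
    m <- generate_measurement(coh[i, ], cfg, 1)
    out <- process_measurement(m$record, m$ref$height_cm, m$ref$bmi)
    expect_true(out$qc$accepted)
    # noise test cannot fire without noise
    expect_equal(sum(out$beats$noise_fail), 0)
    # residual flags come only from boundary-of-beat fiducial geometry
    expect_lt(out$qc$abnormal_fraction, 0.2)
  }
})

test_that("QC rejection grows monotonically with waveform noise", {
  rates <- vapply(c(0.005, 0.05, 0.25), function(nz) {
    cfg <- synth_config(n_subjects = 2, duration_s = 40, seed = 29,
                        noise_sd = nz)
    coh <- sample_cohort(cfg)
    coh$pi_level <- pmax(coh$pi_level, 0.012)
    bad <- 0; tot <- 0
    for (i in 1:2) {
      m <- generate_measurement(coh[i, ], cfg, 1)
      q <- flag_abnormal_beats(
        beat_quality(analyze_beats(m$record), m$ref$height_cm, cfg$fs))
      bad <- bad + sum(q$abnormal | q$noise_fail); tot <- tot + nrow(q)
    }
    bad / tot
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_lt(rates[1], 0.2)
  expect_gt(rates[3], 0.5)
})

test_that("morphology couples monotonically to pressure across a cohort", {
  cfg <- synth_config(n_subjects = 40, duration_s = 20, seed = 37)
  coh <- sample_cohort(cfg)
  feats <- purrr::map_dfr(seq_len(nrow(coh)), function(i) {
    m <- generate_measurement(coh[i, ], cfg, 1)
    q <- beat_quality(analyze_beats(m$record), m$ref$height_cm, cfg$fs)
    ok <- is.na(q$flags)
    tibble::tibble(
      si = median(q$si[ok], na.rm = TRUE),
      b_a = median(purrr::map_dbl(q$sdptg[ok], ~ .x$b_amp / .x$a_amp)),
      sbp = m$ref$sbp_eff)
  })
  expect_gt(cor(feats$sbp, feats$si, method = "spearman"), 0.5)
  expect_gt(cor(feats$sbp, -feats$b_a, method = "spearman"), 0.5)
})

test_that("corruption modes are seeded, manifested, and trip the right rules", {
  cfg <- synth_config(n_subjects = 1, duration_s = 60, seed = 41)
  coh <- sample_cohort(cfg)
  coh$pi_level <- 0.02
  m <- generate_measurement(coh[1, ], cfg, 1)

  c1 <- corrupt_record(m, "spike", beat_fraction = 0.25, seed = 2)
  c2 <- corrupt_record(m, "spike", beat_fraction = 0.25, seed = 2)
  expect_identical(c1$record$samples, c2$record$samples)
  expect_identical(c1$manifest, c2$manifest)

  # 25% spiked beats: the 20% rule rejects the measurement
  out <- process_measurement(c1$record, m$ref$height_cm, m$ref$bmi)
  expect_false(out$qc$accepted)
  expect_match(out$qc$reject_reasons, "abnormal")

  # 10% spiked beats: accepted, and the flagged set covers the corrupted set
  c3 <- corrupt_record(m, "spike", beat_fraction = 0.10, seed = 3)
  out3 <- process_measurement(c3$record, m$ref$height_cm, m$ref$bmi)
  expect_true(out3$qc$accepted)
  flagged <- out3$beats$beat_idx[out3$beats$abnormal]
  spiked_windows <- m$truth[m$truth$beat_idx %in% c3$manifest, ]
  hit <- vapply(seq_len(nrow(spiked_windows)), function(k) {
    w <- spiked_windows[k, ]
    any(out3$beats$start_idx[out3$beats$abnormal] < w$start_idx + w$n &
        out3$beats$end_idx[out3$beats$abnormal] > w$start_idx)
  }, logical(1))
  expect_true(all(hit))

  # heavy diastolic-segment noise fails the SDPTG noise test in those beats
  c4 <- corrupt_record(m, "diastolic_noise", beat_fraction = 0.3,
                       magnitude = 3, seed = 4)
  out4 <- process_measurement(c4$record, m$ref$height_cm, m$ref$bmi)
  noisy <- out4$beats[out4$beats$noise_fail, ]
  expect_gt(nrow(noisy), 0)

  expect_error(corrupt_record(m, "gamma"), "arg")
})
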