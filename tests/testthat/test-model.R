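test_that("target perturbation stays within half a mmHg and is seeded", {
  x <- perturb_targets(130, 30, seed = 1)
  expect_length(x, 30)
  expect_true(all(x >= 129.5 & x <= 130.5))
  expect_identical(perturb_targets(130, 1, seed = 42),
                   perturb_targets(130, 1, seed = 42))
  big <- perturb_targets(130, 1e5, seed = 9)
  se <- sd(big) / sqrt(1e5)
  expect_lt(abs(mean(big) - 130), 3 * se)
  # uniform moments: sd of U(-0.5, 0.5) is 1/sqrt(12)
  expect_equal(sd(big), 1 / sqrt(12), tolerance = 0.02)
})

test_that("constant targets yield constant predictions within the band", {
  beats <- make_beat_table(n_meas = 4, beats_per_meas = 12)
  ref <- tibble::tibble(measurement_id = sprintf("M%02d", 1:4),
                        ref_sbp = 120, ref_dbp = 70)
  est <- bp_train(beats, ref, n_trees = 25, seed = 1)
  p <- predict(est, beats)
  expect_true(all(abs(p$pred_sbp - 120) <= 0.5))
  expect_true(all(abs(p$pred_dbp - 70) <= 0.5))
  # with perturbation disabled the targets are truly degenerate
  expect_warning(bp_train(beats, ref, n_trees = 5, seed = 1, half_width = 0),
                 "degenerate")
})

test_that("a noiseless monotone feature is recovered below the noise floor", {
  n_meas <- 24
  sbp <- seq(95, 175, length.out = n_meas)
  beats <- make_beat_table(n_meas = n_meas, beats_per_meas = 10, seed = 2,
                           si_from_sbp = function(s) s / 12, sbp = sbp)
  ref <- tibble::tibble(measurement_id = sprintf("M%02d", 1:n_meas),
                        ref_sbp = sbp, ref_dbp = 60 + sbp / 4)
  est <- bp_train(beats, ref, n_trees = 50, seed = 3)
  p <- predict(est, beats)
  ord <- match(p$measurement_id, ref$measurement_id)
  rmse <- sqrt(mean((p$pred_sbp - ref$ref_sbp[ord])^2))
  expect_lt(rmse, 5)
  expect_gt(cor(p$pred_sbp, ref$ref_sbp[ord]), 0.95)
})

test_that("training and prediction are invariant to row order", {
  beats <- make_beat_table(n_meas = 6, beats_per_meas = 10, seed = 4)
  ref <- tibble::tibble(measurement_id = sprintf("M%02d", 1:6),
                        ref_sbp = c(110, 118, 126, 134, 150, 162),
                        ref_dbp = c(70, 74, 78, 82, 88, 95))
  est1 <- bp_train(beats, ref, n_trees = 25, seed = 5)
  withr::with_seed(6, perm <- sample(nrow(beats)))
  est2 <- bp_train(beats[perm, ], ref[sample(6), ], n_trees = 25, seed = 5)
  p1 <- predict(est1, beats)
  p2 <- predict(est2, beats[rev(seq_len(nrow(beats))), ])
  expect_equal(p1, p2)
})

test_that("per-measurement aggregation is the median of per-beat outputs", {
  beats <- make_beat_table(n_meas = 2, beats_per_meas = 10, seed = 7)
  ref <- tibble::tibble(measurement_id = c("M01", "M02"),
                        ref_sbp = c(110, 150), ref_dbp = c(70, 90))
  est <- bp_train(beats, ref, n_trees = 25, seed = 8)
  p <- predict(est, beats, per_beat = TRUE)
  for (i in 1:2) {
    expect_equal(p$pred_sbp[i], median(p$beat_preds[[i]]$sbp))
  }
})

test_that("tidy and glance summarise the estimator", {
  beats <- make_beat_table(n_meas = 3, beats_per_meas = 10, seed = 9)
  ref <- tibble::tibble(measurement_id = sprintf("M%02d", 1:3),
                        ref_sbp = c(110, 130, 150), ref_dbp = c(70, 80, 90))
  est <- bp_train(beats, ref, n_trees = 25, seed = 10)
  td <- tidy(est)
  expect_identical(td$pressure, c("sbp", "dbp"))
  gl <- glance(est)
  expect_equal(gl$n_measurements, 3)
  expect_equal(gl$n_beats, 30)
})

test_that("LOSO runs one fold per subject and refuses tiny cohorts", {
  beats <- make_beat_table(n_meas = 10, beats_per_meas = 10, seed = 11)
  # 5 subjects (2 measurements each) from the fixture layout
  ref <- tibble::tibble(
    measurement_id = sprintf("M%02d", 1:10),
    subject_id = sprintf("S%02d", (1:10 + 1) %/% 2),
    ref_sbp = seq(100, 160, length.out = 10),
    ref_dbp = seq(65, 95, length.out = 10))
  out <- loso_validate(beats, ref, n_trees = 25, seed = 12)
  expect_equal(sort(unique(out$fold)), sprintf("S%02d", 1:5))
  expect_equal(nrow(out), 10)
  expect_equal(out$err_sbp, out$pred_sbp - out$ref_sbp)
  two <- beats[beats$subject_id %in% c("S01", "S02"), ]
  expect_error(loso_validate(two, ref), class = "ppgbp_input_error")
})

test_that("calibration factors are medians and self-centre exactly", {
  expect_equal(calibration_factor(c(5, 3, 7)), 5)
  expect_equal(calibration_factor(4), 4)
  expect_equal(calibration_factor(c(-2, 2)), 0)
  expect_error(calibration_factor(numeric(0)), class = "ppgbp_input_error")
  expect_equal(apply_calibration(130, 5), 125)
  expect_equal(apply_calibration(130, 0), 130)
  # median self-centring: calibrating on the factor's own data zeroes the
  # median error
  withr::with_seed(13, errs <- rnorm(9, 4, 3))
  f <- calibration_factor(errs)
  expect_equal(median(errs - f), 0)
})

test_that("calibrate_loso splits per subject and centres calibration data", {
  withr::with_seed(14, {
    loso <- tibble::tibble(
      subject_id = rep(sprintf("S%02d", 1:6), each = 4),
      measurement_id = sprintf("%s_M%d", subject_id, rep(1:4, 6)),
      ref_sbp = 120, ref_dbp = 75,
      pred_sbp = 120 + rep(rnorm(6, 0, 6), each = 4) + rnorm(24, 0, 2),
      pred_dbp = 75 + rep(rnorm(6, 0, 4), each = 4) + rnorm(24, 0, 1.5))
  })
  loso$err_sbp <- loso$pred_sbp - loso$ref_sbp
  loso$err_dbp <- loso$pred_dbp - loso$ref_dbp
  cal <- calibrate_loso(loso)
  expect_equal(nrow(cal$heldout), 12)  # 2 held out per subject
  expect_equal(cal$factors$n_prior, rep(2L, 6))
  # factor = median of that subject's calibration-set errors
  s1 <- loso[loso$subject_id == "S01", ][1:2, ]
  expect_equal(cal$factors$sbp_factor[1], median(s1$err_sbp))
  expect_equal(cal$heldout$cal_sbp, cal$heldout$pred_sbp - cal$heldout$sbp_factor)
})
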