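test_that("resample_beat interpolates linearly and preserves endpoints", {
  y <- sin(seq(0, 2, length.out = 32))
  expect_identical(resample_beat(y, 32), y)
  ramp <- 0:63
  out <- resample_beat(ramp, 32)
  expect_length(out, 32)
  expect_equal(out[1], 0)
  expect_equal(out[32], 63)
  expect_equal(out, seq(0, 63, length.out = 32))  # linearity
  expect_error(resample_beat(1:3), class = "ppgbp_input_error")
})

test_that("resampling respects the interpolation error bound", {
  # smooth oracle: resample a densely sampled sine and compare with the
  # analytic values; error bounded by h^2/8 * max|f''| of the dense grid
  x <- seq(0, 2 * pi, length.out = 101)
  r <- resample_beat(sin(x), 32)
  truth <- sin(seq(0, 2 * pi, length.out = 32))
  bound <- (2 * pi / 100)^2 / 8
  expect_lt(max(abs(r - truth)), bound + 1e-12)
})

test_that("the template is the pointwise median and is order-invariant", {
  shp <- lapply(1:9, function(i) rep(i, 32))
  expect_equal(build_template(shp), rep(5, 32))
  one <- sin(seq(0, 3, length.out = 32))
  expect_equal(build_template(list(one, one, one)), one)
  withr::with_seed(2, {
    shapes <- lapply(1:11, function(i) rnorm(32))
    perm <- sample(11)
  })
  expect_equal(build_template(shapes), build_template(shapes[perm]))
  # 9 clean + 1 corrupted: median ignores the corruption
  clean <- cos(seq(0, 2, length.out = 32))
  shapes <- c(replicate(9, clean, simplify = FALSE), list(clean + 100))
  expect_equal(build_template(shapes), clean)
  expect_error(build_template(list()), class = "ppgbp_input_error")
})

test_that("select_beats keeps the k nearest to the template, earlier on ties", {
  tmpl <- rep(0, 32)
  shapes <- lapply(seq(0.1, 3, length.out = 30), function(d) rep(d / sqrt(32), 32))
  expect_equal(select_beats(shapes, tmpl, 30), 1:30)
  # 40 candidates, 10 distorted
  withr::with_seed(6, {
    base <- lapply(1:40, function(i) rnorm(32, 0, 0.05))
  })
  distorted <- sample(40, 10)
  for (i in distorted) base[[i]] <- base[[i]] + 5
  sel <- select_beats(base, rep(0, 32), 30)
  expect_setequal(sel, setdiff(1:40, distorted))
  # tie for the last slot goes to the earlier index
  shapes <- c(lapply(1:2, function(i) rep(0, 32)),
              list(rep(1, 32)), list(rep(1, 32)))
  expect_equal(select_beats(shapes, rep(0, 32), 3), 1:3)
  # global optimality of the selected set
  d <- vapply(base, function(s) sqrt(sum(s^2)), numeric(1))
  expect_lte(max(d[sel]), min(d[setdiff(1:40, sel)]))
  expect_error(select_beats(base[1:20], rep(0, 32), 30), class = "ppgbp_qc_error")
})

test_that("SVD basis is orthonormal and reports explained variance", {
  withr::with_seed(9, {
    latent <- rnorm(40)
    shapes <- lapply(latent, function(z) z * sin(seq(0, 3, length.out = 32)))
  })
  b1 <- fit_waveform_basis(shapes, 1)
  expect_equal(b1$explained_variance[1], 1, tolerance = 1e-12)
  # orthogonal two-cluster toy set: two components explain everything
  e1 <- c(rep(1, 16), rep(0, 16)); e2 <- c(rep(0, 16), rep(1, 16))
  withr::with_seed(10, {
    shapes2 <- lapply(1:30, function(i) rnorm(1) * e1 + rnorm(1) * e2)
  })
  b2 <- fit_waveform_basis(shapes2, 2)
  expect_equal(sum(b2$explained_variance), 1, tolerance = 1e-12)
  # orthonormality to 1e-8
  withr::with_seed(11, shapes3 <- lapply(1:50, function(i) rnorm(32)))
  b8 <- fit_waveform_basis(shapes3, 8)
  gram <- crossprod(b8$components)
  expect_lt(max(abs(gram - diag(8))), 1e-8)
  # complete basis reconstructs exactly
  ball <- fit_waveform_basis(shapes3, 32)
  x <- shapes3[[7]]
  co <- project_beat(x, ball)
  expect_equal(as.numeric(ball$mean_shape + ball$components %*% co), x,
               tolerance = 1e-8)
  # rank deficiency is an error
  expect_error(fit_waveform_basis(shapes, 3), class = "ppgbp_input_error")
})

test_that("projection recovers known coefficients", {
  withr::with_seed(12, shapes <- lapply(1:40, function(i) rnorm(32)))
  b <- fit_waveform_basis(shapes, 4)
  expect_equal(project_beat(b$mean_shape, b), rep(0, 4))
  x <- b$mean_shape + 2 * b$components[, 1]
  expect_equal(project_beat(x, b), c(2, 0, 0, 0), tolerance = 1e-12)
  co <- c(1.5, -2, 0.25, 3)
  x2 <- b$mean_shape + as.numeric(b$components %*% co)
  expect_equal(project_beat(x2, b), co, tolerance = 1e-12)
})

test_that("reconstruction error is non-increasing in component count", {
  withr::with_seed(13, shapes <- lapply(1:60, function(i) rnorm(32)))
  x <- shapes[[5]]
  errs <- vapply(c(2, 4, 8, 16, 32), function(k) {
    b <- fit_waveform_basis(shapes, k)
    co <- project_beat(x, b)
    sqrt(sum((x - (b$mean_shape + as.numeric(b$components %*% co)))^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("Takazawa ratios are signed amplitude ratios", {
  sd2 <- list(a_amp = 2, b_amp = -1, c_amp = 0.4, d_amp = -0.2, e_amp = 0.1,
              flag = NA_character_)
  expect_equal(sdptg_ratios(sd2),
               c(b_a = -0.5, c_a = 0.2, d_a = -0.1, e_a = 0.05))
  sd2$a_amp <- 0
  expect_error(sdptg_ratios(sd2), class = "ppgbp_qc_error")
  expect_error(sdptg_ratios(list(flag = "sdptg_incomplete")),
               class = "ppgbp_qc_error")
})

test_that("the feature vector has exactly 19 named elements", {
  v <- assemble_features(p = 1:4 / 10, s = 1:8 / 10, hr = 72,
                         ratios = c(b_a = -0.8, c_a = 0.2, d_a = -0.1, e_a = 0.05),
                         si = 7.5, bmi = 24)
  expect_length(v, 19)
  expect_identical(names(v), feature_names())
  expect_error(
    assemble_features(1:4, 1:8, 72, c(b_a = NaN, c_a = 0, d_a = 0, e_a = 0),
                      7.5, 24),
    class = "ppgbp_qc_error")
})

test_that("feature extraction is deterministic", {
  cfg <- synth_config(n_subjects = 1, duration_s = 30, seed = 21)
  coh <- sample_cohort(cfg)
  m <- generate_measurement(coh[1, ], cfg, 1)
  a <- process_measurement(m$record, m$ref$height_cm, m$ref$bmi)
  b <- process_measurement(m$record, m$ref$height_cm, m$ref$bmi)
  expect_identical(a$selected, b$selected)
  expect_identical(a$qc, b$qc)
})
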