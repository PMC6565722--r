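#' Summarise estimation errors against the reference
#'
#' Mean and sample SD of the errors (prediction minus reference), Pearson
#' correlation between prediction and reference, and Bland–Altman bias with
#' 95% limits of agreement (bias +/- 1.96 SD).
#'
#' @param data data frame of paired values.
#' @param pred,ref column names (tidy-eval) of prediction and reference.
#' @return one-row tibble: `n`, `mean_error`, `sd_error`, `pearson_r`,
#'   `ba_bias`, `ba_lo`, `ba_hi`. `pearson_r` is `NA` when the reference is
#'   constant (undefined correlation).
#' @export
#' @examples
#' summarize_errors(data.frame(p = c(1, 2, 3), r = c(1, 2, 3)), p, r)
summarize_errors <- function(data, pred, ref) {
  p <- dplyr::pull(data, {{ pred }})
  r <- dplyr::pull(data, {{ ref }})
  if (length(p) < 2) abort("need at least 2 paired values", class = "ppgbp_input_error")
  e <- p - r
  m <- mean(e)
  s <- sd(e)
  rr <- if (sd(r) == 0 || sd(p) == 0) NA_real_ else cor(p, r)
  tibble(n = length(e), mean_error = m, sd_error = s, pearson_r = rr,
         ba_bias = m, ba_lo = m - 1.96 * s, ba_hi = m + 1.96 * s)
}

#' Assign age, SBP and perfusion strata
#'
#' Age: young (<= 50 y) vs older (> 50 y). Reference SBP: group I
#' (90 < SBP < 120), group II (120 <= SBP < 140), group III (SBP >= 140),
#' with an explicit `below_range` bucket for SBP <= 90 (never silently
#' dropped). Perfusion: low (PI < 0.01) vs high (PI >= 0.01).
#'
#' @param data data frame with `age`, `ref_sbp` and a perfusion column.
#' @param pi_col name of the perfusion-index column (default `mean_pi`;
#'   `pi_level` also common).
#' @param age_cut,sbp_cuts,pi_cut stratum boundaries.
#' @return `data` with factor columns `age_group`, `sbp_group`, `pi_group`.
#' @export
stratify_measurements <- function(data, pi_col = "mean_pi", age_cut = 50,
                                  sbp_cuts = c(90, 120, 140), pi_cut = 0.01) {
  pi_v <- data[[pi_col]]
  data$age_group <- factor(ifelse(data$age <= age_cut, "young", "older"),
                           levels = c("young", "older"))
  data$sbp_group <- factor(
    dplyr::case_when(
      data$ref_sbp <= sbp_cuts[1] ~ "below_range",
      data$ref_sbp < sbp_cuts[2] ~ "I",
      data$ref_sbp < sbp_cuts[3] ~ "II",
      TRUE ~ "III"
    ), levels = c("below_range", "I", "II", "III"))
  data$pi_group <- factor(ifelse(pi_v < pi_cut, "low", "high"),
                          levels = c("low", "high"))
  data
}

#' Two-sample t-test comparing errors between perfusion groups
#'
#' @param errors_low,errors_high numeric error vectors for the low-PI and
#'   high-PI groups (each n >= 2).
#' @return one-row tibble: group means/SDs, `t`, `df`, `p_value`,
#'   `significant` (p < 0.05), `very_significant` (p < 0.001).
#' @export
compare_pi_groups <- function(errors_low, errors_high) {
  if (length(errors_low) < 2 || length(errors_high) < 2) {
    abort("both groups need n >= 2", class = "ppgbp_input_error")
  }
  if (sd(errors_low) == 0 && sd(errors_high) == 0) {
    return(tibble(n_low = length(errors_low), n_high = length(errors_high),
                  mean_low = mean(errors_low), mean_high = mean(errors_high),
                  sd_low = 0, sd_high = 0, t = NA_real_, df = NA_real_,
                  p_value = NA_real_, significant = NA, very_significant = NA))
  }
  tt <- t.test(errors_low, errors_high)
  tibble(
    n_low = length(errors_low), n_high = length(errors_high),
    mean_low = mean(errors_low), mean_high = mean(errors_high),
    sd_low = sd(errors_low), sd_high = sd(errors_high),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < 0.05,
    very_significant = tt$p.value < 0.001
  )
}

#' One-sided paired t-test: does calibration shrink absolute errors?
#'
#' Tests whether the absolute calibrated errors are smaller than the
#' absolute calibration-free errors on the same measurements (alternative:
#' mean of |free| - |calibrated| > 0).
#'
#' @param errors_free,errors_cal paired numeric error vectors.
#' @return one-row tibble: `n`, `mean_abs_free`, `mean_abs_cal`, `t`, `df`,
#'   `p_value`, `significant`, `very_significant`.
#' @export
compare_calibration <- function(errors_free, errors_cal) {
  if (length(errors_free) != length(errors_cal)) {
    abort("error vectors must be paired (equal length)",
          class = "ppgbp_input_error")
  }
  if (length(errors_free) < 2) {
    abort("need at least 2 pairs", class = "ppgbp_input_error")
  }
  d <- abs(errors_free) - abs(errors_cal)
  if (sd(d) == 0) {
    # degenerate: identical improvement on every pair (or none at all)
    tt <- list(statistic = c(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf),
               parameter = c(df = length(d) - 1),
               p.value = if (mean(d) > 0) 0 else if (mean(d) < 0) 1 else 0.5)
  } else {
    tt <- t.test(d, alternative = "greater")
  }
  tibble(
    n = length(d),
    mean_abs_free = mean(abs(errors_free)),
    mean_abs_cal = mean(abs(errors_cal)),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < 0.05,
    very_significant = tt$p.value < 0.001
  )
}

#' Stratified evaluation report
#'
#' Builds the four table families of a calibration-free vs calibrated
#' evaluation: error summaries by age group, by SBP group within age group,
#' by perfusion group within age group, and (when calibrated errors are
#' supplied) calibration-free vs calibrated. Empty strata appear with n = 0
#' and no statistics.
#'
#' @param loso stratified tibble from [loso_validate()] +
#'   [stratify_measurements()].
#' @param calibrated optional held-out tibble from [calibrate_loso()].
#' @return named list of tibbles: `by_age`, `by_sbp_group`, `by_pi_group`,
#'   and `calibration` when available.
#' @export
bp_report <- function(loso, calibrated = NULL) {
  sum_or_empty <- function(df, pred, ref) {
    if (nrow(df) >= 2) summarize_errors(df, {{ pred }}, {{ ref }})
    else tibble(n = nrow(df), mean_error = NA_real_, sd_error = NA_real_,
                pearson_r = NA_real_, ba_bias = NA_real_, ba_lo = NA_real_,
                ba_hi = NA_real_)
  }
  both <- function(df) {
    dplyr::bind_rows(
      dplyr::mutate(sum_or_empty(df, .data$pred_sbp, .data$ref_sbp),
                    pressure = "sbp", .before = 1),
      dplyr::mutate(sum_or_empty(df, .data$pred_dbp, .data$ref_dbp),
                    pressure = "dbp", .before = 1)
    )
  }
  by_age <- loso %>%
    dplyr::group_by(.data$age_group) %>%
    dplyr::group_modify(~ both(.x)) %>% dplyr::ungroup()
  by_sbp <- loso %>%
    dplyr::group_by(.data$age_group, .data$sbp_group, .drop = FALSE) %>%
    dplyr::group_modify(~ both(.x)) %>% dplyr::ungroup()
  by_pi <- loso %>%
    dplyr::group_by(.data$age_group, .data$pi_group, .drop = FALSE) %>%
    dplyr::group_modify(~ both(.x)) %>% dplyr::ungroup()
  out <- list(by_age = by_age, by_sbp_group = by_sbp, by_pi_group = by_pi)
  if (!is.null(calibrated) && nrow(calibrated) >= 2) {
    free <- dplyr::bind_rows(
      dplyr::mutate(summarize_errors(calibrated, .data$pred_sbp, .data$ref_sbp),
                    pressure = "sbp", variant = "calibration_free", .before = 1),
      dplyr::mutate(summarize_errors(calibrated, .data$pred_dbp, .data$ref_dbp),
                    pressure = "dbp", variant = "calibration_free", .before = 1))
    cal <- dplyr::bind_rows(
      dplyr::mutate(summarize_errors(calibrated, .data$cal_sbp, .data$ref_sbp),
                    pressure = "sbp", variant = "calibrated", .before = 1),
      dplyr::mutate(summarize_errors(calibrated, .data$cal_dbp, .data$ref_dbp),
                    pressure = "dbp", variant = "calibrated", .before = 1))
    out$calibration <- dplyr::bind_rows(free, cal)
    out$calibration_test <- dplyr::bind_rows(
      dplyr::mutate(compare_calibration(calibrated$err_sbp, calibrated$cal_err_sbp),
                    pressure = "sbp", .before = 1),
      dplyr::mutate(compare_calibration(calibrated$err_dbp, calibrated$cal_err_dbp),
                    pressure = "dbp", .before = 1))
  }
  lows <- loso$pi_group == "low"
  if (sum(lows) >= 2 && sum(!lows) >= 2) {
    out$pi_test <- dplyr::bind_rows(
      dplyr::mutate(compare_pi_groups(loso$err_sbp[lows], loso$err_sbp[!lows]),
                    pressure = "sbp", .before = 1),
      dplyr::mutate(compare_pi_groups(loso$err_dbp[lows], loso$err_dbp[!lows]),
                    pressure = "dbp", .before = 1))
  }
  out
}
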