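#' Agreement scatter plot of estimated vs reference pressure
#'
#' @param data tibble with prediction and reference columns.
#' @param pred,ref tidy-eval column names.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_agreement <- function(data, pred, ref, title = "Estimated vs reference BP") {
  ggplot2::ggplot(data, ggplot2::aes({{ ref }}, {{ pred }})) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "steelblue") +
    ggplot2::labs(x = "Reference BP (mmHg)", y = "Estimated BP (mmHg)",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Bland–Altman plot of estimation errors
#'
#' The x-axis is the reference pressure (agreement against the cuff), the
#' y-axis the difference (estimate minus reference); horizontal lines mark
#' the bias and the 95% limits of agreement.
#'
#' @param data tibble with prediction and reference columns.
#' @param pred,ref tidy-eval column names.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_bland_altman <- function(data, pred, ref, title = "Bland-Altman") {
  p <- dplyr::pull(data, {{ pred }})
  r <- dplyr::pull(data, {{ ref }})
  e <- p - r
  bias <- mean(e)
  lo <- bias - 1.96 * sd(e)
  hi <- bias + 1.96 * sd(e)
  ggplot2::ggplot(tibble(ref = r, diff = e), ggplot2::aes(.data$ref, .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(lo, hi), linetype = 2) +
    ggplot2::labs(x = "Reference BP (mmHg)", y = "Estimate - reference (mmHg)",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Plot a PPG beat with its fiducial points
#'
#' @param y numeric beat samples.
#' @param fs sampling rate, Hz.
#' @param peak_idx,notch_idx fiducial indices (optional).
#' @return a ggplot object.
#' @export
plot_beat <- function(y, fs, peak_idx = NULL, notch_idx = NULL) {
  df <- tibble(t = (seq_along(y) - 1) / fs, y = y)
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "PPG (counts)") +
    ggplot2::theme_minimal()
  marks <- tibble(t = numeric(0), y = numeric(0), what = character(0))
  if (!is.null(peak_idx) && !is.na(peak_idx)) {
    marks <- dplyr::add_row(marks, t = (peak_idx - 1) / fs, y = y[peak_idx],
                            what = "systolic peak")
  }
  if (!is.null(notch_idx) && !is.na(notch_idx)) {
    marks <- dplyr::add_row(marks, t = (notch_idx - 1) / fs, y = y[notch_idx],
                            what = "dicrotic notch")
  }
  if (nrow(marks)) {
    g <- g + ggplot2::geom_point(data = marks,
                                 ggplot2::aes(colour = .data$what), size = 2) +
      ggplot2::labs(colour = NULL)
  }
  g
}
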