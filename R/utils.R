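#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Runs of the pipeline are driven by one master seed; every stochastic
#' sub-step (a LOSO fold, a measurement's target perturbation, a subject's
#' waveform noise) derives its own seed deterministically from the master
#' seed plus string labels. This makes full runs reproducible and insensitive
#' to the order in which sub-steps execute.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the sub-step.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "fold", "S003")
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  label <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                        character(1)), collapse = "/")
  m <- 2147483563
  h <- as.numeric(master) %% m
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer(h %% (m - 1)) + 1L
}

#' Pipe operator
#'
#' @importFrom dplyr %>%
#' @name %>%
#' @rdname pipe
#' @export
NULL

# local maxima / minima of a numeric vector (interior, strict on one side so
# flat-topped plateaus report their first sample)
local_extrema <- function(x, kind = c("max", "min")) {
  kind <- match.arg(kind)
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  if (kind == "max") {
    idx <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  } else {
    idx <- i[x[i] < x[i - 1] & x[i] <= x[i + 1]]
  }
  idx
}

# trapezoidal area scaled to seconds
trapz_area <- function(y, fs) {
  if (length(y) < 2) return(0)
  pracma::trapz(seq_along(y), y) / fs
}

# sub-sample refinement of an extremum position by parabolic interpolation;
# at 50 Hz integer fiducials quantize interval features (e.g. the stiffness
# index) badly enough to break robust outlier scales
refine_extremum <- function(y, i) {
  n <- length(y)
  if (is.na(i) || i <= 1 || i >= n) return(as.numeric(i))
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (den == 0) return(as.numeric(i))
  off <- 0.5 * (y[i - 1] - y[i + 1]) / den
  i + max(-0.5, min(0.5, off))
}

# robust per-feature scale: scaled MAD with an IQR fallback when the MAD
# degenerates to zero on quantized data
robust_scale <- function(v) {
  s <- mad(v, na.rm = TRUE)
  if (!is.na(s) && s == 0) s <- stats::IQR(v, na.rm = TRUE) / 1.349
  s
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a finite scalar in [%g, %g]", name, lo, hi),
          class = "ppgbp_config_error")
  }
  invisible(x)
}
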