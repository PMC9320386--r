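#' Bland-Altman agreement analysis
#'
#' Quantifies agreement between a reference device and the app on paired
#' readings. Differences are defined as `test - reference` (app minus
#' device), so a positive bias means the app over-reads relative to the
#' device. Limits of agreement are `bias +/- conf_mult * sd` with the
#' sample standard deviation (n - 1 denominator) of the differences.
#'
#' @param reference Numeric vector of reference-device readings.
#' @param test Numeric vector of app readings, same length, `n >= 2`.
#' @param conf_mult Limit multiplier; the default 1.96 gives normal 95%
#'   limits of agreement.
#' @return An object of class `bland_altman` with `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n`, and a `points` data frame of per-pair
#'   `(mean, diff)` plotting coordinates.
#' @export
bland_altman <- function(reference, test, conf_mult = 1.96) {
  reference <- as.numeric(reference)
  test <- as.numeric(test)
  if (length(reference) != length(test)) {
    stop("reference and test readings differ in length")
  }
  if (length(reference) < 2L) {
    stop("limits of agreement need at least 2 pairs")
  }
  if (anyNA(reference) || anyNA(test) ||
      any(!is.finite(c(reference, test)))) {
    stop("all paired readings must be finite")
  }
  d <- test - reference
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         loa_low = bias - conf_mult * sd_diff,
         loa_high = bias + conf_mult * sd_diff,
         n = length(d), conf_mult = conf_mult,
         points = data.frame(mean = (reference + test) / 2, diff = d)),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias (test - reference): %.4f\n", x$bias))
  cat(sprintf("  sd of differences:       %.4f\n", x$sd_diff))
  cat(sprintf("  limits of agreement:     [%.4f, %.4f]\n",
              x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, main = "Bland-Altman plot", ...) {
  plot(x$points$mean, x$points$diff,
       xlab = "Mean of reference and test",
       ylab = "Difference (test - reference)",
       main = main, ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high),
                   lty = c(2, 1, 2))
  invisible(x)
}

#' Average accuracy over repeated runs
#'
#' Arithmetic mean of per-run accuracy percentages, as used to summarize
#' repeated confusion-matrix evaluations into a single figure.
#'
#' @param values Non-empty numeric vector of percentages.
#' @return The mean percentage (full precision; round to two decimals
#'   for display).
#' @export
mean_of_runs <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no run accuracies supplied")
  if (anyNA(values)) stop("run accuracies must not be NA")
  mean(values)
}
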