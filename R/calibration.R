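#' Construct a calibration curve
#'
#' One analyte's response model: the optimized color channel whose
#' response `Y` is most linear in concentration `X`, the fitted formula
#' `Y = slope * X + intercept` (or `Y = slope * log10(X) + intercept`),
#' its coefficient of determination, and the concentration interval over
#' which the formula is valid (the linearity range -- readings outside it
#' are clamped and flagged).
#'
#' @param analyte Analyte name.
#' @param channel Optimized channel, one of `R, G, B, H, S, V`.
#' @param scale `"linear"` or `"log10"`: the transform applied to
#'   concentration before the linear fit.
#' @param slope,intercept Fitted coefficients in response units; `slope`
#'   must be nonzero so the curve can be inverted.
#' @param r_squared Coefficient of determination in `[0, 1]`.
#' @param linearity_range Length-2 numeric `c(xmin, xmax)` in
#'   concentration units; `xmin > 0` when `scale = "log10"`.
#' @param reference_range Free-text normal range (may be `NA`).
#' @param units Concentration units label.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(analyte, channel, scale, slope, intercept,
                              r_squared = NA_real_,
                              linearity_range, reference_range = NA_character_,
                              units = "") {
  scale <- match.arg(scale, c("linear", "log10"))
  if (!(channel %in% CHANNEL_ORDER)) {
    stop("unknown channel '", channel, "'")
  }
  if (!is.numeric(slope) || !is.finite(slope) || slope == 0) {
    stop("a flat curve (slope = 0) cannot be inverted")
  }
  lr <- as.numeric(linearity_range)
  if (length(lr) != 2L || anyNA(lr) || lr[1] >= lr[2]) {
    stop("`linearity_range` must be c(xmin, xmax) with xmin < xmax")
  }
  if (scale == "log10" && lr[1] <= 0) {
    stop("log10-scale curves need xmin > 0")
  }
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1)) {
    stop("`r_squared` must lie in [0, 1]")
  }
  structure(
    list(analyte = analyte, channel = channel, scale = scale,
         slope = slope, intercept = intercept, r_squared = r_squared,
         linearity_range = lr, reference_range = as.character(reference_range),
         units = units),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  xlab <- if (x$scale == "log10") "log10(X)" else "X"
  cat(sprintf("<calibration_curve %s: %s-channel Y = %g * %s + %g, r2 = %s, linear %g-%g %s>\n",
              x$analyte, x$channel, x$slope, xlab, x$intercept,
              format(x$r_squared), x$linearity_range[1], x$linearity_range[2],
              x$units))
  invisible(x)
}

#' Evaluate a calibration curve's forward formula
#'
#' The noiseless channel response the curve predicts at a concentration:
#' `slope * x + intercept`, with `x` the concentration or its log10
#' depending on the curve's scale.
#'
#' @param curve A [calibration_curve()].
#' @param concentration Numeric vector of concentrations (positive when
#'   the curve is log10-scaled).
#' @return Numeric vector of predicted channel responses.
#' @export
forward_response <- function(curve, concentration) {
  stopifnot(inherits(curve, "calibration_curve"))
  x <- as.numeric(concentration)
  if (any(!is.finite(x))) stop("concentrations must be finite")
  if (curve$scale == "log10") {
    if (any(x <= 0)) stop("log10-scale curves need positive concentrations")
    x <- log10(x)
  }
  curve$slope * x + curve$intercept
}

#' Fit a per-channel calibration line by ordinary least squares
#'
#' Regresses channel response on concentration (or log10 concentration)
#' and reports slope, intercept and `r^2 = 1 - SSres/SStot`. When the
#' responses have zero variance, `r^2` is defined as 1 if the residuals
#' are zero and 0 otherwise, keeping the fit a total function.
#'
#' @param concentrations Numeric vector, positive when `scale = "log10"`.
#' @param responses Numeric vector of channel responses, same length.
#' @param scale `"linear"` or `"log10"`.
#' @return An object of class `fit_result` with fields `slope`,
#'   `intercept`, `r_squared`, `n_points`.
#' @export
fit_curve <- function(concentrations, responses, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  x <- as.numeric(concentrations)
  y <- as.numeric(responses)
  if (length(x) != length(y)) stop("concentrations and responses differ in length")
  if (length(x) < 2L) stop("need at least 2 points to fit a line")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("concentrations and responses must be finite")
  }
  if (scale == "log10") {
    if (any(x <= 0)) stop("log10 scale requires positive concentrations")
    x <- log10(x)
  }
  if (length(unique(x)) < 2L) {
    stop("all x-values identical: cannot fit a slope")
  }
  fit <- stats::lm(y ~ x)
  coefs <- stats::coef(fit)
  ssres <- sum(stats::residuals(fit)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot == 0) {
    if (ssres < 1e-10) 1 else 0
  } else {
    max(0, min(1, 1 - ssres / sstot))
  }
  structure(
    list(slope = unname(coefs[2]), intercept = unname(coefs[1]),
         r_squared = r2, n_points = length(x)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result slope = %g, intercept = %g, r2 = %g, n = %d>\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Select the optimized channel by linearity
#'
#' Picks the channel whose fit has the highest `r^2`; ties break by the
#' fixed channel order R, G, B, H, S, V.
#'
#' @param fits Named list of [fit_curve()] results keyed by channel.
#' @return The selected channel name.
#' @export
select_optimized_channel <- function(fits) {
  if (length(fits) == 0L) stop("no channel fits supplied")
  chans <- names(fits)
  if (is.null(chans) || !all(chans %in% CHANNEL_ORDER)) {
    stop("`fits` must be named by channels R, G, B, H, S, V")
  }
  ord <- CHANNEL_ORDER[CHANNEL_ORDER %in% chans]
  r2 <- vapply(fits[ord], function(f) f$r_squared, numeric(1))
  ord[which.max(r2)]
}

#' Fit every requested channel of a concentration series
#'
#' Screens RGB and/or HSV channels for linearity against concentration,
#' enabling side-by-side comparison of color spaces before a channel is
#' committed to a panel.
#'
#' @param data Data frame with columns `concentration`, `r`, `g`, `b`
#'   (such as produced by [dilution_series()]).
#' @param channels Channels to screen, subset of `R, G, B, H, S, V`.
#' @param scale `"linear"` or `"log10"`.
#' @return Named list of `fit_result`, keyed by channel.
#' @export
screen_linearity <- function(data, channels = c("R", "G", "B"),
                             scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(data),
            all(c("concentration", "r", "g", "b") %in% names(data)))
  if (!all(channels %in% CHANNEL_ORDER)) stop("unknown channel requested")
  resp <- vapply(seq_len(nrow(data)), function(i) {
    col <- c(data$r[i], data$g[i], data$b[i])
    vapply(channels, channel_value, numeric(1), color = col)
  }, numeric(length(channels)))
  resp <- matrix(resp, nrow = length(channels))
  out <- lapply(seq_along(channels), function(k) {
    fit_curve(data$concentration, resp[k, ], scale = scale)
  })
  names(out) <- channels
  out
}

# Optimized channel, formula, r-squared, linearity and reference range
# for the seven analytes of the built-in panel. "log" ranges use log10.
BUILTIN_PANEL_SPEC <- list(
  list("pH",         "R", "linear", -40.9,   432.7, 0.9442, c(5, 9),       "4.8-7.4",   "pH"),
  list("Glucose",    "B", "linear", -0.3983, 122.8, 0.9104, c(50, 300),    "<20 mg/dL", "mg/dL"),
  list("Ketones",    "G", "log10",  -69.92,  189.1, 0.9872, c(5, 100),     "<5 mg/dL",  "mg/dL"),
  list("Hemoglobin", "R", "linear", -141.1,  217,   0.9461, c(0.25, 1.0),  NA,          "ug/mL"),
  list("Bilirubin",  "G", "linear", -22.36,  195.2, 0.9025, c(0.5, 3.0),   "<0.2 mg/dL","mg/dL"),
  list("Protein",    "R", "log10",  -48.88,  208.3, 0.9682, c(10, 1000),   "<2 mg/dL",  "mg/dL"),
  list("Nitrites",   "G", "log10",  -53,     131,   0.963,  c(1, 100),     NA,          "mg/dL")
)

#' The built-in seven-analyte dipstick panel
#'
#' Calibration curves for pH, glucose, ketones, hemoglobin, bilirubin,
#' protein (albumin) and nitrites, each carrying the optimized channel,
#' fitted formula, r-squared, linearity range and reference range
#' established on dilution series of artificial urine.
#'
#' @return Named list of 7 [calibration_curve()] objects.
#' @export
builtin_panel <- function() {
  out <- lapply(BUILTIN_PANEL_SPEC, function(p) {
    calibration_curve(analyte = p[[1]], channel = p[[2]], scale = p[[3]],
                      slope = p[[4]], intercept = p[[5]], r_squared = p[[6]],
                      linearity_range = p[[7]], reference_range = p[[8]],
                      units = p[[9]])
  })
  names(out) <- vapply(out, function(cv) cv$analyte, character(1))
  out
}
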