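#' Construct a semi-quantitative category scheme
#'
#' Ordered concentration bins for one analyte. Bins are half-open
#' `[edge_i, edge_{i+1})`: a concentration below the first edge takes the
#' first label, at or above the last edge the last label, so each edge
#' belongs to its upper bin and categorization is deterministic.
#'
#' @param analyte Analyte name.
#' @param edges Strictly increasing numeric vector of internal bin edges
#'   in concentration units.
#' @param labels Character vector of category labels, one more than
#'   `edges` (e.g. negative / trace / + / ++).
#' @return An object of class `category_scheme`.
#' @export
category_scheme <- function(analyte, edges, labels) {
  edges <- as.numeric(edges)
  if (length(edges) < 1L || anyNA(edges) || any(diff(edges) <= 0)) {
    stop("`edges` must be strictly increasing")
  }
  if (length(labels) != length(edges) + 1L) {
    stop("need exactly one more label than edges")
  }
  if (anyDuplicated(labels)) stop("category labels must be unique")
  structure(list(analyte = analyte, edges = edges,
                 labels = as.character(labels)),
            class = "category_scheme")
}

#' Default category scheme for a built-in analyte
#'
#' First edge at the analyte's reference-range cutoff where one is
#' printed, remaining edges at the linearity-range endpoints. pH is
#' graded on its clinical normal range instead of a negative/positive
#' ladder. Hemoglobin and nitrites have no printed cutoff, so their
#' schemes use linearity endpoints only. All schemes are overridable in
#' the panel configuration.
#'
#' @param analyte One of the built-in panel's analyte names.
#' @return A [category_scheme()].
#' @export
default_scheme <- function(analyte) {
  switch(analyte,
    "pH"         = category_scheme("pH", c(4.8, 7.4),
                                   c("acidic", "normal", "alkaline")),
    "Glucose"    = category_scheme("Glucose", c(20, 50, 300),
                                   c("negative", "trace", "+", "++")),
    "Ketones"    = category_scheme("Ketones", c(5, 100),
                                   c("negative", "+", "++")),
    "Hemoglobin" = category_scheme("Hemoglobin", c(0.25, 1.0),
                                   c("negative", "+", "++")),
    "Bilirubin"  = category_scheme("Bilirubin", c(0.2, 0.5, 3.0),
                                   c("negative", "trace", "+", "++")),
    "Protein"    = category_scheme("Protein", c(2, 10, 1000),
                                   c("negative", "trace", "+", "++")),
    "Nitrites"   = category_scheme("Nitrites", c(1, 100),
                                   c("negative", "+", "++")),
    stop("no default category scheme for analyte '", analyte, "'")
  )
}

#' Invert a calibration curve (inverse prediction)
#'
#' Solves the calibration formula for concentration given a measured
#' channel response: `X = (Y - intercept)/slope` on the linear scale, or
#' `X = 10^((Y - intercept)/slope)` on the log10 scale. Estimates outside
#' the linearity range -- the limit of reliable color processing -- are
#' clamped to the range with an explicit flag rather than rejected, so
#' the caveat travels with the value.
#'
#' @param curve A [calibration_curve()].
#' @param response Measured channel response (scalar, finite).
#' @return List with `concentration` (clamped to the linearity range) and
#'   `clamped` (logical).
#' @export
predict_concentration <- function(curve, response) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.numeric(response) || length(response) != 1L || !is.finite(response)) {
    stop("`response` must be a single finite number")
  }
  xfit <- (response - curve$intercept) / curve$slope
  xhat <- if (curve$scale == "log10") 10^xfit else xfit
  lo <- curve$linearity_range[1]
  hi <- curve$linearity_range[2]
  # a relative epsilon keeps round-tripped boundary values unflagged
  tol <- 1e-9 * max(abs(lo), abs(hi), 1)
  clamped <- xhat < lo - tol || xhat > hi + tol
  list(concentration = min(max(xhat, lo), hi), clamped = clamped)
}

#' Map a concentration to its semi-quantitative category
#'
#' @param scheme A [category_scheme()].
#' @param concentration Finite numeric scalar (or vector).
#' @return Character label(s) of the half-open bin containing the value.
#' @export
categorize <- function(scheme, concentration) {
  stopifnot(inherits(scheme, "category_scheme"))
  x <- as.numeric(concentration)
  if (anyNA(x) || any(!is.finite(x))) stop("concentration must be finite")
  scheme$labels[findInterval(x, scheme$edges) + 1L]
}

#' Read a full dipstick strip from an image
#'
#' For every analyte in the panel configuration: extract the pad's mean
#' color from its ROI, take the calibration curve's optimized channel as
#' the response, invert the curve to a concentration, and map it to a
#' category. A pad that fails (e.g. a degenerate ROI) is flagged in its
#' row without aborting the remaining pads.
#'
#' @param image A [pad_image()].
#' @param config A [panel_config()] carrying curves, ROIs and schemes.
#' @param stat Color aggregation passed to [extract_pad_color()].
#' @return Data frame with one row per analyte: `analyte`, `r`, `g`, `b`,
#'   `channel`, `response`, `concentration`, `clamped`, `category`,
#'   `failed`, `error`.
#' @export
read_strip <- function(image, config, stat = "mean") {
  stopifnot(inherits(image, "pad_image"), inherits(config, "panel_config"))
  rows <- lapply(names(config$analytes), function(a) {
    entry <- config$analytes[[a]]
    tryCatch({
      col <- extract_pad_color(image, entry$roi, stat = stat)
      y <- channel_value(col, entry$curve$channel)
      pred <- predict_concentration(entry$curve, y)
      data.frame(analyte = a, r = col[["r"]], g = col[["g"]], b = col[["b"]],
                 channel = entry$curve$channel, response = y,
                 concentration = pred$concentration, clamped = pred$clamped,
                 category = categorize(entry$scheme, pred$concentration),
                 failed = FALSE, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(analyte = a, r = NA_real_, g = NA_real_, b = NA_real_,
                 channel = entry$curve$channel, response = NA_real_,
                 concentration = NA_real_, clamped = NA,
                 category = NA_character_, failed = TRUE,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
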