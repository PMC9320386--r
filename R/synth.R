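#' Sensor noise model for synthetic pad colors
#'
#' Additive Gaussian noise per channel on the 0-255 scale, plus a single
#' multiplicative illumination gain applied to all channels, emulating
#' the environment-dependent variation of smartphone captures. Default
#' sd of 2 channel units keeps noiseless tests exact and noisy data
#' realistic for an 8-bit camera sensor.
#'
#' @param channel_sd Gaussian sd per channel, `>= 0` (0-255 scale).
#' @param gain Global illumination gain, `> 0`.
#' @param seed Optional integer seed; when set, generators that take this
#'   model reproduce their output exactly.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(channel_sd = 2, gain = 1, seed = NULL) {
  if (!is.numeric(channel_sd) || channel_sd < 0) stop("`channel_sd` must be >= 0")
  if (!is.numeric(gain) || gain <= 0) stop("`gain` must be > 0")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(channel_sd = channel_sd, gain = gain, seed = seed),
            class = "noise_model")
}

with_model_seed <- function(noise, expr) {
  if (is.null(noise$seed)) expr else withr::with_seed(noise$seed, expr)
}

# Forward models for the two channels a calibration curve does not
# describe. Each ramp is base + amp * t^2 with t the position in [0, 1]
# along the curve's fit scale, i.e. a gentle curvature that keeps those
# channels visibly responsive while strictly less linear than the
# optimized channel, so channel selection remains identifiable from
# synthetic series. Values chosen to stay within [0, 255] at gain 1 and
# give plausible reagent-pad hues.
PAD_RAMPS <- list(
  pH         = list(G = c(180, -90),  B = c(60, 80)),
  Glucose    = list(R = c(120, 70),   G = c(160, -80)),
  Ketones    = list(R = c(210, -120), B = c(120, -60)),
  Hemoglobin = list(G = c(170, -110), B = c(90, -40)),
  Bilirubin  = list(R = c(230, -60),  B = c(110, -70)),
  Protein    = list(G = c(190, -70),  B = c(70, 60)),
  Nitrites   = list(R = c(250, -80),  B = c(180, -90))
)
DEFAULT_RAMP <- c(140, -60)

# noiseless mean RGB triplet for one pad at one concentration
pad_mean_color <- function(curve, concentration) {
  lo <- curve$linearity_range[1]
  hi <- curve$linearity_range[2]
  if (concentration < lo || concentration > hi) {
    stop(sprintf("concentration %g outside the %s linearity range [%g, %g]",
                 concentration, curve$analyte, lo, hi))
  }
  tpos <- if (curve$scale == "log10") {
    (log10(concentration) - log10(lo)) / (log10(hi) - log10(lo))
  } else {
    (concentration - lo) / (hi - lo)
  }
  ramps <- PAD_RAMPS[[curve$analyte]]
  col <- c(r = NA_real_, g = NA_real_, b = NA_real_)
  col[tolower(curve$channel)] <- forward_response(curve, concentration)
  for (ch in c("r", "g", "b")) {
    if (is.na(col[ch])) {
      p <- ramps[[toupper(ch)]]
      if (is.null(p)) p <- DEFAULT_RAMP
      col[ch] <- p[1] + p[2] * tpos^2
    }
  }
  col
}

clip_channels <- function(x) {
  n_clipped <- sum(x < 0 | x > 255)
  structure(pmin(pmax(x, 0), 255), n_clipped = n_clipped)
}

simulate_pad_color_impl <- function(curve, concentration, noise) {
  mu <- pad_mean_color(curve, concentration)
  raw <- noise$gain * mu +
    if (noise$channel_sd > 0) stats::rnorm(3, 0, noise$channel_sd) else 0
  out <- clip_channels(unname(raw))
  names(out) <- c("r", "g", "b")
  out
}

#' Simulate one pad color at a known concentration
#'
#' The curve's optimized channel takes `gain * (forward formula)` plus
#' Gaussian sensor noise; the two remaining channels follow fixed,
#' documented per-analyte ramps plus the same noise. All channels are
#' clipped to `[0, 255]`; the number of clipped channels is attached as
#' attribute `n_clipped`.
#'
#' @param curve A [calibration_curve()].
#' @param concentration Concentration inside the curve's linearity range.
#' @param noise A [noise_model()]; a set seed makes the call reproducible.
#' @return Named numeric RGB vector `c(r =, g =, b =)`.
#' @export
simulate_pad_color <- function(curve, concentration, noise = noise_model()) {
  stopifnot(inherits(curve, "calibration_curve"), inherits(noise, "noise_model"))
  with_model_seed(noise, simulate_pad_color_impl(curve, concentration, noise))
}

#' Render a synthetic dipstick image
#'
#' Lays one square pad per analyte in panel order along a horizontal
#' strip; each pixel draws its own Gaussian noise around the pad's mean
#' color. The exact fractional ROIs of the pads are returned with the
#' image, so the render/read round trip is exact at zero noise.
#'
#' @param config A [panel_config()].
#' @param concentrations Named numeric vector or list, one concentration
#'   per analyte in the panel.
#' @param noise A [noise_model()].
#' @param pad_size Pad edge length in pixels.
#' @param shrink ROI shrink fraction recorded in the returned ROIs.
#' @return List with `image` (a [pad_image()]) and `rois` (named list of
#'   [roi()], one per analyte).
#' @export
render_strip <- function(config, concentrations, noise = noise_model(),
                         pad_size = 20, shrink = 0.2) {
  stopifnot(inherits(config, "panel_config"), inherits(noise, "noise_model"))
  analytes <- names(config$analytes)
  missing <- setdiff(analytes, names(concentrations))
  if (length(missing) > 0L) {
    stop("no concentration given for: ", paste(missing, collapse = ", "))
  }
  n <- length(analytes)
  with_model_seed(noise, {
    px <- array(0, dim = c(pad_size, n * pad_size, 3L))
    for (i in seq_len(n)) {
      curve <- config$analytes[[i]]$curve
      mu <- noise$gain * pad_mean_color(curve, concentrations[[analytes[i]]])
      cols <- ((i - 1L) * pad_size + 1L):(i * pad_size)
      for (ch in 1:3) {
        vals <- mu[ch] + if (noise$channel_sd > 0) {
          stats::rnorm(pad_size^2, 0, noise$channel_sd)
        } else 0
        px[, cols, ch] <- matrix(pmin(pmax(vals, 0), 255), nrow = pad_size)
      }
    }
    rois <- lapply(seq_len(n), function(i) {
      roi((i - 1) / n, 0, i / n, 1, shrink = shrink)
    })
    names(rois) <- analytes
    list(image = pad_image(px), rois = rois)
  })
}

#' Generate a synthetic dilution series
#'
#' Emulates the dilution-series protocol used to calibrate each analyte:
#' pad colors are simulated at each standard concentration level, with
#' `replicates` independent noisy pads per level.
#'
#' @param curve A [calibration_curve()].
#' @param levels Concentrations within the linearity range; the default
#'   is 5 levels spanning the range, evenly spaced on the curve's fit
#'   scale (log-spaced for log10 curves).
#' @param replicates Pads per level, `>= 1`.
#' @param noise A [noise_model()].
#' @return Data frame with columns `concentration`, `r`, `g`, `b`,
#'   ordered by level then replicate.
#' @export
dilution_series <- function(curve, levels = default_levels(curve),
                            replicates = 1, noise = noise_model()) {
  stopifnot(inherits(curve, "calibration_curve"), replicates >= 1)
  with_model_seed(noise, {
    rows <- lapply(rep(levels, each = replicates), function(x) {
      col <- simulate_pad_color_impl(curve, x, noise)
      data.frame(concentration = x, r = col[["r"]], g = col[["g"]],
                 b = col[["b"]])
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Standard concentration levels spanning a curve's linearity range
#'
#' @param curve A [calibration_curve()].
#' @param n Number of levels.
#' @return Numeric vector of `n` concentrations, evenly spaced on the
#'   curve's fit scale.
#' @export
default_levels <- function(curve, n = 5) {
  lo <- curve$linearity_range[1]
  hi <- curve$linearity_range[2]
  if (curve$scale == "log10") {
    10^seq(log10(lo), log10(hi), length.out = n)
  } else {
    seq(lo, hi, length.out = n)
  }
}

#' Concentration levels at the center of each usable category bin
#'
#' For each bin of the scheme that intersects the curve's linearity
#' range, the midpoint of the intersection on the curve's fit scale
#' (geometric midpoint for log10 curves). These are the standard levels
#' at which reference exemplars are learned.
#'
#' @param scheme A [category_scheme()].
#' @param curve The analyte's [calibration_curve()].
#' @return Data frame with columns `label` and `concentration`.
#' @export
bin_centers <- function(scheme, curve) {
  stopifnot(inherits(scheme, "category_scheme"),
            inherits(curve, "calibration_curve"))
  lo <- curve$linearity_range[1]
  hi <- curve$linearity_range[2]
  bounds <- c(-Inf, scheme$edges, Inf)
  rows <- lapply(seq_along(scheme$labels), function(i) {
    a <- max(bounds[i], lo)
    b <- min(bounds[i + 1L], hi)
    # bins are half-open [lower, upper): a point sitting exactly on the
    # upper bound belongs to the next bin, so a degenerate intersection
    # there is empty
    if (a > b || (a == b && a >= bounds[i + 1L])) return(NULL)
    mid <- if (curve$scale == "log10") sqrt(a * b) else (a + b) / 2
    data.frame(label = scheme$labels[i], concentration = mid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a paired device-vs-app dataset
#'
#' Emulates the comparison protocol against the reference urine
#' analyzer: for every analyte, `n` pads are simulated at standard
#' concentration levels and labeled with the true semi-quantitative
#' category; the device label equals the true category except that with
#' probability `label_noise_rate` it is flipped to an adjacent category
#' (emulating device reads at bin boundaries).
#'
#' @param config A [panel_config()].
#' @param n Samples per analyte, `>= 1`.
#' @param noise A [noise_model()].
#' @param label_noise_rate Adjacent-flip probability in `[0, 1]`.
#' @param sampling `"levels"` (default) draws uniformly among the
#'   analyte's category bin-center levels, emulating repeated tests of
#'   standard solutions; `"uniform"` draws concentrations uniformly over
#'   the linearity range on the curve's fit scale.
#' @return Data frame with columns `analyte`, `concentration`, `r`, `g`,
#'   `b`, `true_category`, `device_label`.
#' @export
paired_device_dataset <- function(config, n, noise = noise_model(),
                                  label_noise_rate = 0,
                                  sampling = c("levels", "uniform")) {
  stopifnot(inherits(config, "panel_config"), n >= 1,
            label_noise_rate >= 0, label_noise_rate <= 1)
  sampling <- match.arg(sampling)
  with_model_seed(noise, {
    rows <- lapply(names(config$analytes), function(a) {
      entry <- config$analytes[[a]]
      curve <- entry$curve
      scheme <- entry$scheme
      lo <- curve$linearity_range[1]
      hi <- curve$linearity_range[2]
      concs <- if (sampling == "levels") {
        centers <- bin_centers(scheme, curve)
        sample(centers$concentration, n, replace = TRUE)
      } else if (curve$scale == "log10") {
        10^stats::runif(n, log10(lo), log10(hi))
      } else {
        stats::runif(n, lo, hi)
      }
      sub <- lapply(concs, function(x) {
        col <- simulate_pad_color_impl(curve, x, noise)
        truth <- categorize(scheme, x)
        dev <- truth
        if (label_noise_rate > 0 && stats::runif(1) < label_noise_rate) {
          i <- match(truth, scheme$labels)
          nb <- intersect(c(i - 1L, i + 1L), seq_along(scheme$labels))
          dev <- scheme$labels[nb[sample.int(length(nb), 1L)]]
        }
        data.frame(analyte = a, concentration = x, r = col[["r"]],
                   g = col[["g"]], b = col[["b"]], true_category = truth,
                   device_label = dev, stringsAsFactors = FALSE)
      })
      do.call(rbind, sub)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
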