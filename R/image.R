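#' Construct a pad image from a pixel array
#'
#' A `pad_image` is an 8-bit RGB pixel grid, stored as a
#' `height x width x 3` numeric array on the 0-255 scale, row-major with
#' the origin at the top-left (row 1 = top of the image).
#'
#' @param pixels Numeric array `height x width x 3` with values in
#'   `[0, 255]`, or a `height x width` matrix (grayscale, replicated
#'   across the three channels).
#' @return An object of class `pad_image` with fields `width`, `height`
#'   and `pixels`.
#' @export
pad_image <- function(pixels) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3L] < 3L) {
    stop("`pixels` must be a height x width x 3 array or a matrix")
  }
  pixels <- pixels[, , 1:3, drop = FALSE]
  d <- dim(pixels)
  if (d[1L] < 1L || d[2L] < 1L) {
    stop("image must have width >= 1 and height >= 1")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]")
  }
  structure(
    list(width = d[2L], height = d[1L], pixels = pixels),
    class = "pad_image"
  )
}

#' @export
print.pad_image <- function(x, ...) {
  cat(sprintf("<pad_image %d x %d px (w x h), 8-bit RGB>\n", x$width, x$height))
  invisible(x)
}

#' Load a pad image from a PNG or JPEG file
#'
#' Decodes an 8-bit RGB image. Alpha channels are discarded; grayscale
#' images are replicated across the three channels. PNG files are read
#' with the \pkg{png} package; JPEG files require \pkg{EBImage}.
#'
#' @param path Path to a PNG (`.png`) or JPEG (`.jpg`/`.jpeg`) file.
#' @return A [pad_image()].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("image file not found: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- tryCatch(png::readPNG(path),
      error = function(e) stop("failed to decode PNG '", path, "': ",
                               conditionMessage(e)))
    px <- raw * 255
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("reading JPEG requires the EBImage package")
    }
    img <- tryCatch(EBImage::readImage(path),
      error = function(e) stop("failed to decode JPEG '", path, "': ",
                               conditionMessage(e)))
    d <- EBImage::imageData(img) * 255
    # EBImage stores pixels x-major; transpose to row-major
    px <- if (length(dim(d)) == 2L) t(d) else aperm(d, c(2L, 1L, 3L))
  } else {
    stop("unsupported image format '", ext, "' (PNG or JPEG expected)")
  }
  pad_image(pmin(pmax(px, 0), 255))
}

#' Define a fractional region of interest
#'
#' A `roi` locates one reagent pad as a half-open rectangle
#' `[x0, x1) x [y0, y1)` in fractions of image width and height, so the
#' same panel configuration applies at any image resolution. `shrink`
#' trims that fraction of the rectangle's own extent off each edge before
#' averaging, to avoid pad borders and shadows.
#'
#' @param x0,y0,x1,y1 Rectangle corners as fractions in `[0, 1]` with
#'   `x0 < x1`, `y0 < y1`.
#' @param shrink Fraction in `[0, 0.5)` trimmed from each edge.
#' @return An object of class `roi`.
#' @export
roi <- function(x0, y0, x1, y1, shrink = 0.2) {
  vals <- c(x0, y0, x1, y1)
  if (anyNA(vals) || any(vals < 0) || any(vals > 1)) {
    stop("ROI corners must be fractions in [0, 1]")
  }
  if (x0 >= x1 || y0 >= y1) stop("ROI requires x0 < x1 and y0 < y1")
  if (is.na(shrink) || shrink < 0 || shrink >= 0.5) {
    stop("`shrink` must lie in [0, 0.5)")
  }
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1, shrink = shrink),
            class = "roi")
}

# fractional ROI -> 1-based pixel index ranges, after shrink;
# floor(frac * dim) rounding, half-open in pixel space
roi_pixels <- function(r, width, height) {
  wf <- r$x1 - r$x0
  hf <- r$y1 - r$y0
  sx0 <- r$x0 + r$shrink * wf
  sx1 <- r$x1 - r$shrink * wf
  sy0 <- r$y0 + r$shrink * hf
  sy1 <- r$y1 - r$shrink * hf
  px0 <- floor(sx0 * width)
  px1 <- floor(sx1 * width)
  py0 <- floor(sy0 * height)
  py1 <- floor(sy1 * height)
  if (px1 <= px0 || py1 <= py0) {
    stop("ROI contains no pixels after shrink at this resolution")
  }
  list(cols = (px0 + 1L):px1, rows = (py0 + 1L):py1)
}

#' Extract the representative pad color from an image region
#'
#' Reduces all pixels inside the (shrunken) ROI to one RGB triplet by
#' per-channel arithmetic mean (or median, for robustness to specular
#' outliers).
#'
#' @param image A [pad_image()].
#' @param roi A [roi()] valid for the image.
#' @param stat Aggregation: `"mean"` (default) or `"median"`.
#' @return Named numeric vector `c(r =, g =, b =)` on the 0-255 scale;
#'   means may be non-integer.
#' @export
extract_pad_color <- function(image, roi, stat = c("mean", "median")) {
  stopifnot(inherits(image, "pad_image"), inherits(roi, "roi"))
  stat <- match.arg(stat)
  idx <- roi_pixels(roi, image$width, image$height)
  agg <- if (stat == "mean") mean else stats::median
  out <- vapply(1:3, function(ch) {
    agg(image$pixels[idx$rows, idx$cols, ch])
  }, numeric(1))
  names(out) <- c("r", "g", "b")
  out
}
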