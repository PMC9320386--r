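CHANNEL_ORDER <- c("R", "G", "B", "H", "S", "V")

#' Convert an RGB triplet to HSV
#'
#' Standard hexcone conversion: value is `max/255`, saturation is
#' `(max - min)/max` (0 for black), and hue comes from the
#' dominant-channel sector formula. The hue of achromatic colors
#' (r = g = b) is defined as 0 degrees so the conversion is total and
#' HSV components can serve as regression responses.
#'
#' @param color Numeric length-3 RGB vector on the 0-255 scale.
#' @return Named numeric vector `c(h =, s =, v =)` with hue in degrees
#'   `[0, 360)` and saturation/value in `[0, 1]`.
#' @export
rgb_to_hsv <- function(color) {
  color <- validate_rgb(color)
  hsv <- grDevices::rgb2hsv(color[1], color[2], color[3], maxColorValue = 255)
  c(h = (unname(hsv["h", 1]) * 360) %% 360,
    s = unname(hsv["s", 1]),
    v = unname(hsv["v", 1]))
}

validate_rgb <- function(color) {
  color <- as.numeric(color)
  if (length(color) != 3L || anyNA(color) || any(!is.finite(color))) {
    stop("an RGB triplet must be 3 finite numbers")
  }
  if (any(color < 0) || any(color > 255)) {
    stop("RGB components must lie in [0, 255]")
  }
  color
}

#' Extract one color-space component as a scalar response
#'
#' Returns the named component of the triplet: `R`, `G`, `B` directly on
#' the 0-255 scale, or `H` (degrees), `S`, `V` (unit scale) computed on
#' demand. This scalar is the response `Y` used by calibration curves.
#'
#' @param color Numeric length-3 RGB vector on the 0-255 scale.
#' @param channel One of `"R"`, `"G"`, `"B"`, `"H"`, `"S"`, `"V"`.
#' @return A single numeric response.
#' @export
channel_value <- function(color, channel) {
  if (!is.character(channel) || length(channel) != 1L ||
      !(channel %in% CHANNEL_ORDER)) {
    stop("`channel` must be one of ", paste(CHANNEL_ORDER, collapse = ", "))
  }
  color <- validate_rgb(color)
  if (channel %in% c("R", "G", "B")) {
    return(unname(color[match(channel, c("R", "G", "B"))]))
  }
  unname(rgb_to_hsv(color)[match(channel, c("H", "S", "V"))])
}
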