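# shared fixture builders: everything is generated in code at test time

write_png_fixture <- function(pixels, path = tempfile(fileext = ".png")) {
  png::writePNG(pixels / 255, path)
  path
}

# small random 8-bit image as a height x width x 3 array
random_pixels <- function(h, w, seed) {
  withr::with_seed(seed, array(sample(0:255, h * w * 3, replace = TRUE),
                               dim = c(h, w, 3)))
}

full_roi <- function(shrink = 0) roi(0, 0, 1, 1, shrink = shrink)

# mid-range concentrations for the built-in panel
mid_concentrations <- function(cfg = panel_config()) {
  vapply(cfg$analytes, function(e) default_levels(e$curve, 3)[2], numeric(1))
}
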