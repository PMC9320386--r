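#' Assemble a panel configuration
#'
#' A `panel_config` ties together, per analyte: the calibration curve,
#' the pad's fractional ROI on the strip image, and the category scheme,
#' plus free-form capture metadata (illuminance, distance, device, ...).
#' Analytes omitted from `curves`/`rois`/`schemes` fall back to the
#' built-in panel curve, evenly spaced strip ROIs, and the default
#' scheme.
#'
#' @param analytes Character vector of unique analyte names; defaults to
#'   the built-in panel's seven analytes.
#' @param curves Optional named list of [calibration_curve()].
#' @param rois Optional named list of [roi()].
#' @param schemes Optional named list of [category_scheme()].
#' @param name Panel name.
#' @param metadata Free-form named list of capture metadata.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(analytes = names(builtin_panel()),
                         curves = list(), rois = list(), schemes = list(),
                         name = "default", metadata = list()) {
  if (anyDuplicated(analytes)) {
    stop("duplicate analyte in panel: ",
         paste(unique(analytes[duplicated(analytes)]), collapse = ", "))
  }
  builtin <- builtin_panel()
  n <- length(analytes)
  entries <- lapply(seq_len(n), function(i) {
    a <- analytes[i]
    curve <- curves[[a]]
    if (is.null(curve)) {
      curve <- builtin[[a]]
      if (is.null(curve)) stop("no calibration curve given for '", a, "'")
    }
    stopifnot(inherits(curve, "calibration_curve"))
    r <- rois[[a]]
    if (is.null(r)) r <- roi((i - 1) / n, 0, i / n, 1)
    stopifnot(inherits(r, "roi"))
    sch <- schemes[[a]]
    if (is.null(sch)) sch <- default_scheme(a)
    stopifnot(inherits(sch, "category_scheme"))
    list(curve = curve, roi = r, scheme = sch)
  })
  names(entries) <- analytes
  structure(list(name = name, metadata = metadata, analytes = entries),
            class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat(sprintf("<panel_config '%s': %d analytes (%s)>\n", x$name,
              length(x$analytes), paste(names(x$analytes), collapse = ", ")))
  invisible(x)
}

curve_to_list <- function(cv) {
  list(analyte = cv$analyte, channel = cv$channel, scale = cv$scale,
       slope = cv$slope, intercept = cv$intercept,
       r_squared = cv$r_squared, linearity_range = cv$linearity_range,
       reference_range = cv$reference_range, units = cv$units)
}

curve_from_list <- function(l) {
  calibration_curve(
    analyte = l$analyte, channel = l$channel, scale = l$scale,
    slope = l$slope, intercept = l$intercept,
    r_squared = if (is.null(l$r_squared)) NA_real_ else l$r_squared,
    linearity_range = unlist(l$linearity_range),
    reference_range = if (is.null(l$reference_range)) NA_character_
                      else l$reference_range,
    units = if (is.null(l$units)) "" else l$units)
}

#' Save / load a panel configuration as JSON
#'
#' The JSON schema is one object per analyte carrying all calibration
#' curve fields, the fractional ROI, and the category scheme, plus panel
#' name and capture metadata. `load_config` validates the schema and
#' fills omitted curves, ROIs and schemes with the same defaults as
#' [panel_config()].
#'
#' @param config A [panel_config()].
#' @param path File path.
#' @return `save_config` returns `path` invisibly; `load_config` returns
#'   the validated `panel_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "panel_config"))
  obj <- list(
    name = config$name,
    metadata = config$metadata,
    analytes = lapply(names(config$analytes), function(a) {
      e <- config$analytes[[a]]
      list(analyte = a,
           curve = curve_to_list(e$curve),
           roi = unclass(e$roi),
           scheme = list(edges = e$scheme$edges, labels = e$scheme$labels))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("panel config not found: ", path)
  obj <- tryCatch(jsonlite::read_json(path),
    error = function(e) stop("invalid panel JSON '", path, "': ",
                             conditionMessage(e)))
  if (is.null(obj$analytes) || length(obj$analytes) == 0L) {
    stop("panel config field 'analytes' missing or empty")
  }
  analytes <- vapply(obj$analytes, function(e) {
    if (is.null(e$analyte)) stop("panel entry missing field 'analyte'")
    e$analyte
  }, character(1))
  if (anyDuplicated(analytes)) {
    stop("duplicate analyte in panel config: ",
         paste(unique(analytes[duplicated(analytes)]), collapse = ", "))
  }
  curves <- list(); rois <- list(); schemes <- list()
  for (e in obj$analytes) {
    a <- e$analyte
    if (!is.null(e$curve)) {
      curves[[a]] <- tryCatch(curve_from_list(e$curve),
        error = function(err) stop("invalid curve for '", a, "': ",
                                   conditionMessage(err)))
    }
    if (!is.null(e$roi)) {
      rois[[a]] <- tryCatch(
        roi(e$roi$x0, e$roi$y0, e$roi$x1, e$roi$y1,
            shrink = if (is.null(e$roi$shrink)) 0.2 else e$roi$shrink),
        error = function(err) stop("invalid roi for '", a, "': ",
                                   conditionMessage(err)))
    }
    if (!is.null(e$scheme)) {
      schemes[[a]] <- tryCatch(
        category_scheme(a, unlist(e$scheme$edges), unlist(e$scheme$labels)),
        error = function(err) stop("invalid scheme for '", a, "': ",
                                   conditionMessage(err)))
    }
  }
  panel_config(analytes = analytes, curves = curves, rois = rois,
               schemes = schemes,
               name = if (is.null(obj$name)) "default" else obj$name,
               metadata = if (is.null(obj$metadata)) list() else obj$metadata)
}
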