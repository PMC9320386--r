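#' Cross-tabulate reference vs predicted categories
#'
#' @param reference,predicted Equal-length vectors of category labels,
#'   every label drawn from `classes`.
#' @param classes Ordered vector of all class labels.
#' @return An object of class `confusion_matrix` holding the count
#'   matrix (rows = reference, columns = predicted) and the class order.
#' @export
build_confusion <- function(reference, predicted, classes) {
  reference <- as.character(reference)
  predicted <- as.character(predicted)
  classes <- as.character(classes)
  if (length(reference) != length(predicted)) {
    stop("reference and predicted labels differ in length")
  }
  if (anyDuplicated(classes)) stop("`classes` must be unique")
  bad <- setdiff(unique(c(reference, predicted)), classes)
  if (length(bad) > 0L) {
    stop("labels not in `classes`: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(reference, levels = classes),
                  factor(predicted, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(reference = classes, predicted = classes))
  structure(list(classes = classes, counts = counts),
            class = "confusion_matrix")
}

#' Per-class one-vs-rest TP/FP/TN/FN summaries
#'
#' @param cm A [build_confusion()] result.
#' @return Data frame with columns `class`, `TP`, `FP`, `TN`, `FN`; each
#'   row sums to the matrix total.
#' @export
confusion_summary <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  out <- lapply(seq_along(cm$classes), function(i) {
    tp <- cm$counts[i, i]
    fp <- sum(cm$counts[, i]) - tp
    fn <- sum(cm$counts[i, ]) - tp
    data.frame(class = cm$classes[i], TP = tp, FP = fp,
               TN = total - tp - fp - fn, FN = fn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Overall categorical accuracy of a confusion matrix
#'
#' `100 * trace / total`; in the binary case this equals
#' `100 * (TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param cm A [build_confusion()] result with at least one sample.
#' @return Accuracy percentage in `[0, 100]`.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm$counts)
  if (total == 0L) stop("empty confusion matrix")
  100 * sum(diag(cm$counts)) / total
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = reference, cols = predicted)\n")
  print(x$counts)
  if (sum(x$counts) > 0L) {
    cat(sprintf("accuracy: %.2f%%\n", accuracy(x)))
  }
  invisible(x)
}

#' Create an empty reference store
#'
#' The store realizes the confusion-matrix learning model: readings from
#' the reference analyzer are treated as absolute labels, each labeled
#' pad color is kept as an exemplar, and new measurements are snapped to
#' the nearest learned exemplar. The color distance is Euclidean in RGB
#' with the analyte's optimized channel up-weighted, since that channel
#' carries the calibrated signal.
#'
#' @param panel Named list of [calibration_curve()] (defaults to the
#'   built-in panel) supplying each analyte's optimized channel.
#' @param channel_weight Weight applied to the optimized channel in the
#'   distance (the other channels have weight 1).
#' @param recommended_n Exemplar count per analyte below which the store
#'   is considered immature (surfaced by `print`, never enforced).
#' @return An object of class `reference_store`.
#' @export
reference_store <- function(panel = builtin_panel(), channel_weight = 2,
                            recommended_n = 1000) {
  stopifnot(is.list(panel), length(panel) > 0)
  chans <- vapply(panel, function(cv) cv$channel, character(1))
  names(chans) <- vapply(panel, function(cv) cv$analyte, character(1))
  structure(
    list(channels = chans, channel_weight = channel_weight,
         recommended_n = recommended_n,
         exemplars = stats::setNames(
           rep(list(data.frame(r = numeric(), g = numeric(), b = numeric(),
                               label = character(),
                               stringsAsFactors = FALSE)),
               length(chans)), names(chans)),
         log = data.frame(analyte = character(), predicted = character(),
                          reference = character(), scored = logical(),
                          correct = logical(), stringsAsFactors = FALSE)),
    class = "reference_store"
  )
}

store_weights <- function(store, analyte) {
  w <- c(r = 1, g = 1, b = 1)
  ch <- store$channels[[analyte]]
  if (!is.null(ch) && ch %in% c("R", "G", "B")) {
    w[tolower(ch)] <- store$channel_weight
  }
  w
}

#' Snap a measured color to the nearest learned exemplar
#'
#' Returns the label of the stored exemplar closest to the query color in
#' the weighted RGB distance; ties break deterministically in favor of
#' the earliest-inserted exemplar.
#'
#' @param store A [reference_store()] holding at least one exemplar for
#'   the analyte.
#' @param analyte Analyte name.
#' @param color Numeric length-3 RGB vector on the 0-255 scale.
#' @return The nearest exemplar's category label.
#' @export
snap_to_reference <- function(store, analyte, color) {
  stopifnot(inherits(store, "reference_store"))
  ex <- store$exemplars[[analyte]]
  if (is.null(ex) || nrow(ex) == 0L) {
    stop("no exemplars stored for analyte '", analyte, "'")
  }
  color <- validate_rgb(color)
  w <- store_weights(store, analyte)
  d2 <- w["r"] * (ex$r - color[1])^2 +
        w["g"] * (ex$g - color[2])^2 +
        w["b"] * (ex$b - color[3])^2
  ex$label[which.min(d2)]
}

#' Learn one labeled observation online
#'
#' The store first predicts the new color's category by
#' [snap_to_reference()] and scores the prediction against the reference
#' label, then appends the observation as a new exemplar. An observation
#' whose reference label has not been seen before for that analyte is a
#' cold start for its class: it is logged but not scored, because no
#' exemplar of that class existed to predict it. The scored history
#' yields the running accuracy ([running_accuracy()]), i.e. the degree to
#' which repeated tests keep reproducing the reference reading.
#'
#' @param object A [reference_store()].
#' @param analyte Analyte name.
#' @param color Numeric length-3 RGB vector on the 0-255 scale.
#' @param label Reference-device category label.
#' @param ... Unused.
#' @return The updated store.
#' @export
update.reference_store <- function(object, analyte, color, label, ...) {
  color <- validate_rgb(color)
  if (!is.character(label) || length(label) != 1L || is.na(label)) {
    stop("`label` must be a single category label")
  }
  if (!analyte %in% names(object$exemplars)) {
    object$exemplars[[analyte]] <-
      data.frame(r = numeric(), g = numeric(), b = numeric(),
                 label = character(), stringsAsFactors = FALSE)
  }
  ex <- object$exemplars[[analyte]]
  predicted <- if (nrow(ex) > 0L) {
    snap_to_reference(object, analyte, color)
  } else {
    NA_character_
  }
  scored <- label %in% ex$label
  object$log <- rbind(object$log, data.frame(
    analyte = analyte, predicted = predicted, reference = label,
    scored = scored,
    correct = if (scored) identical(predicted, label) else NA,
    stringsAsFactors = FALSE))
  object$exemplars[[analyte]] <- rbind(ex, data.frame(
    r = color[1], g = color[2], b = color[3], label = label,
    stringsAsFactors = FALSE))
  object
}

#' Running accuracy of the reference store
#'
#' Percentage of scored online predictions that matched the reference
#' label, over the whole store or one analyte.
#'
#' @param store A [reference_store()].
#' @param analyte Optional analyte name to restrict to.
#' @return Accuracy percentage, or `NA` if nothing has been scored yet.
#' @export
running_accuracy <- function(store, analyte = NULL) {
  stopifnot(inherits(store, "reference_store"))
  lg <- store$log
  if (!is.null(analyte)) lg <- lg[lg$analyte == analyte, , drop = FALSE]
  lg <- lg[lg$scored, , drop = FALSE]
  if (nrow(lg) == 0L) return(NA_real_)
  100 * mean(lg$correct)
}

#' Confusion matrix of the store's scored online predictions
#'
#' @param store A [reference_store()].
#' @param analyte Optional analyte name to restrict to.
#' @param classes Class order; defaults to labels in order of first
#'   appearance in the scored log.
#' @return A `confusion_matrix`, or `NULL` if nothing has been scored.
#' @export
store_confusion <- function(store, analyte = NULL, classes = NULL) {
  stopifnot(inherits(store, "reference_store"))
  lg <- store$log
  if (!is.null(analyte)) lg <- lg[lg$analyte == analyte, , drop = FALSE]
  lg <- lg[lg$scored, , drop = FALSE]
  if (nrow(lg) == 0L) return(NULL)
  if (is.null(classes)) {
    classes <- unique(c(lg$reference, lg$predicted))
  }
  build_confusion(lg$reference, lg$predicted, classes)
}

#' @export
print.reference_store <- function(x, ...) {
  n <- vapply(x$exemplars, nrow, integer(1))
  cat(sprintf("<reference_store: %d analytes, %d exemplars>\n",
              length(n), sum(n)))
  acc <- running_accuracy(x)
  if (!is.na(acc)) cat(sprintf("  running accuracy: %.2f%%\n", acc))
  low <- names(n)[n > 0 & n < x$recommended_n]
  if (length(low) > 0L) {
    cat(sprintf("  note: %d analyte(s) below the recommended %d exemplars\n",
                length(low), x$recommended_n))
  }
  invisible(x)
}

#' Save / load a reference store as JSON
#'
#' Exemplar insertion order is preserved so nearest-exemplar tie-breaks
#' stay deterministic across sessions.
#'
#' @param store A [reference_store()].
#' @param path File path.
#' @return `save_store` returns `path` invisibly; `load_store` returns
#'   the store.
#' @export
save_store <- function(store, path) {
  stopifnot(inherits(store, "reference_store"))
  obj <- list(channels = as.list(store$channels),
              channel_weight = store$channel_weight,
              recommended_n = store$recommended_n,
              exemplars = store$exemplars,
              log = store$log)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  if (!file.exists(path)) stop("store file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  empty_ex <- data.frame(r = numeric(), g = numeric(), b = numeric(),
                         label = character(), stringsAsFactors = FALSE)
  ex <- lapply(obj$exemplars, function(e) {
    if (length(e) == 0L || length(e$r) == 0L) return(empty_ex)
    data.frame(r = as.numeric(e$r), g = as.numeric(e$g),
               b = as.numeric(e$b), label = as.character(e$label),
               stringsAsFactors = FALSE)
  })
  lg <- obj$log
  lg <- if (length(lg) == 0L || length(lg$analyte) == 0L) {
    data.frame(analyte = character(), predicted = character(),
               reference = character(), scored = logical(),
               correct = logical(), stringsAsFactors = FALSE)
  } else {
    data.frame(analyte = as.character(lg$analyte),
               predicted = as.character(lg$predicted),
               reference = as.character(lg$reference),
               scored = as.logical(lg$scored),
               correct = as.logical(lg$correct),
               stringsAsFactors = FALSE)
  }
  structure(
    list(channels = unlist(obj$channels),
         channel_weight = obj$channel_weight,
         recommended_n = obj$recommended_n,
         exemplars = ex, log = lg),
    class = "reference_store"
  )
}
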