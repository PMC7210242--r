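## Image and margin classification against the per-patient threshold.

#' Detection result for one field of view
#'
#' @slot marginId,fieldIndex identifiers of the classified field.
#' @slot positive whether the field is called positive.
#' @slot highlightMask logical matrix of the suprathreshold pixels retained
#'   after the minimum-area rule (the pixels shown in red on the display).
#' @slot maxNormalizedSignal maximum smoothed signal divided by the
#'   patient's baseline (or by the threshold when no baseline is supplied).
#' @slot suprathresholdAreaPx number of retained suprathreshold pixels.
#' @export
setClass("DetectionResult",
  representation(marginId = "character", fieldIndex = "integer",
                 positive = "logical", highlightMask = "matrix",
                 maxNormalizedSignal = "numeric",
                 suprathresholdAreaPx = "integer"))

setMethod("show", "DetectionResult", function(object) {
  cat("DetectionResult", object@marginId, "field", object@fieldIndex, ":",
      if (object@positive) "POSITIVE" else "negative", "\n")
  cat("  suprathreshold px:", object@suprathresholdAreaPx,
      " max normalized signal:", signif(object@maxNormalizedSignal, 4), "\n")
})

#' Classify one field of view against a threshold
#'
#' Pixels are smoothed (3x3 exact median by default), compared strictly
#' against the patient's threshold (\code{> threshold}; a pixel exactly at
#' threshold is negative), and suprathreshold pixels are grouped into
#' 8-connected components. The field is positive when the largest component
#' reaches \code{minAreaPx} pixels; the highlight mask keeps exactly the
#' components that reach it.
#'
#' @param field a [MarginField-class] that passed QC.
#' @param threshold the patient's detection threshold, AFU (positive).
#' @param config a [DetectionConfig-class].
#' @param baseline optional baseline estimate (AFU) used to express
#'   \code{maxNormalizedSignal} in baseline units.
#' @return a [DetectionResult-class].
#' @export
classifyImage <- function(field, threshold, config = detectionConfig(),
                          baseline = NA_real_) {
  stopifnot(is(field, "MarginField"))
  if (is.na(threshold) || threshold <= 0)
    stop("threshold must be positive")
  sm <- if (config@smoothing == "median3x3")
    medianSmooth(field@pixels, field@circularMask) else field@pixels
  supra <- !is.na(sm) & sm > threshold & field@circularMask
  keep <- matrix(FALSE, nrow(supra), ncol(supra))
  area <- 0L
  if (any(supra)) {
    lab <- labelComponents(supra)
    sizes <- tabulate(lab[lab > 0L])
    big <- which(sizes >= config@minAreaPx)
    if (length(big)) {
      keep <- matrix(lab %in% big, nrow(lab), ncol(lab))
      area <- as.integer(sum(sizes[big]))
    }
  }
  maxSig <- max(sm[field@circularMask])
  denom <- if (!is.na(baseline)) baseline else threshold
  new("DetectionResult", marginId = field@marginId,
      fieldIndex = field@fieldIndex, positive = area >= config@minAreaPx,
      highlightMask = keep,
      maxNormalizedSignal = maxSig / denom,
      suprathresholdAreaPx = area)
}

#' Aggregate field readings into one margin reading
#'
#' A margin orientation is positive if any of its fields of view shows an
#' area of signal above threshold (several fields are combined for larger
#' cavities).
#'
#' @param results list of [DetectionResult-class], all from the same margin.
#' @return \code{"positive"} or \code{"negative"}.
#' @export
aggregateMargin <- function(results) {
  if (!length(results)) stop("margin aggregation needs at least one field")
  ids <- vapply(results, function(r) r@marginId, character(1))
  if (length(unique(ids)) != 1L)
    stop("fields from different margins cannot be aggregated: ",
         paste(unique(ids), collapse = ", "))
  if (any(vapply(results, function(r) r@positive, logical(1))))
    "positive" else "negative"
}

#' Render the red-highlight display overlay
#'
#' Grayscale rendering of the field (scaled to its in-mask maximum) with the
#' retained suprathreshold pixels painted pure red, exactly as many red
#' pixels as the result's suprathreshold area. Pixels outside the circular
#' field are black.
#'
#' @param field a [MarginField-class].
#' @param result the matching [DetectionResult-class].
#' @return numeric array \code{height x width x 3} (RGB in [0, 1]).
#' @export
renderOverlay <- function(field, result) {
  stopifnot(is(field, "MarginField"), is(result, "DetectionResult"))
  if (!identical(dim(field@pixels), dim(result@highlightMask)) ||
      !identical(field@marginId, result@marginId) ||
      !identical(field@fieldIndex, result@fieldIndex))
    stop("detection result does not belong to this field")
  g <- field@pixels / max(field@pixels[field@circularMask])
  g[!field@circularMask] <- 0
  g <- pmin(g, 1)
  rgb <- array(rep(g, 3L), dim = c(dim(g), 3L))
  hl <- result@highlightMask
  if (any(hl)) {
    idx <- which(hl, arr.ind = TRUE)
    rgb[cbind(idx, 1L)] <- 1
    rgb[cbind(idx, 2L)] <- 0
    rgb[cbind(idx, 3L)] <- 0
  }
  rgb
}
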