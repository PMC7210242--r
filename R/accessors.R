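#' @name accessors
#' @title Accessors for fluorMargin objects
#'
#' @description Slot accessors: use these rather than \code{@}.
#'
#' @param object a fluorMargin S4 object.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "MarginField", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("circularMask", function(object) standardGeneric("circularMask"))
#' @rdname accessors
#' @export
setMethod("circularMask", "MarginField", function(object) object@circularMask)

#' @rdname accessors
#' @export
setGeneric("truthMask", function(object) standardGeneric("truthMask"))
#' @rdname accessors
#' @export
setMethod("truthMask", "MarginField", function(object) object@truthMask)

#' @rdname accessors
#' @export
setGeneric("contactFactor", function(object) standardGeneric("contactFactor"))
#' @rdname accessors
#' @export
setMethod("contactFactor", "MarginField", function(object)
  object@contactFactor)

#' @rdname accessors
#' @export
setGeneric("exVivoReference",
           function(object) standardGeneric("exVivoReference"))
#' @rdname accessors
#' @export
setMethod("exVivoReference", "MarginField", function(object)
  object@exVivoReference)

#' @rdname accessors
#' @export
setGeneric("marginId", function(object) standardGeneric("marginId"))
#' @rdname accessors
#' @export
setMethod("marginId", "MarginField", function(object) object@marginId)
#' @rdname accessors
#' @export
setMethod("marginId", "MarginSurface", function(object) object@marginId)

#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setMethod("patientId", "MarginSurface", function(object) object@patientId)

#' @rdname accessors
#' @export
setGeneric("orientation", function(object) standardGeneric("orientation"))
#' @rdname accessors
#' @export
setMethod("orientation", "MarginSurface", function(object) object@orientation)

#' @rdname accessors
#' @export
setGeneric("stage", function(object) standardGeneric("stage"))
#' @rdname accessors
#' @export
setMethod("stage", "MarginSurface", function(object) object@stage)

#' @rdname accessors
#' @export
setGeneric("fields", function(object) standardGeneric("fields"))
#' @rdname accessors
#' @export
setMethod("fields", "MarginSurface", function(object) object@fields)

#' @rdname accessors
#' @export
setGeneric("histopath", function(object) standardGeneric("histopath"))
#' @rdname accessors
#' @export
setMethod("histopath", "MarginSurface", function(object) object@histopath)

#' @rdname accessors
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))
#' @rdname accessors
#' @export
setMethod("patients", "MarginCohort", function(object) object@patients)

#' @rdname accessors
#' @export
setGeneric("surfaces", function(object) standardGeneric("surfaces"))
#' @rdname accessors
#' @export
setMethod("surfaces", "MarginCohort", function(object) object@surfaces)

#' @rdname accessors
#' @export
setGeneric("initScans", function(object) standardGeneric("initScans"))
#' @rdname accessors
#' @export
setMethod("initScans", "MarginCohort", function(object) object@initScans)

#' @rdname accessors
#' @export
setGeneric("generatorCfg", function(object) standardGeneric("generatorCfg"))
#' @rdname accessors
#' @export
setMethod("generatorCfg", "MarginCohort", function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("coefficient", function(object) standardGeneric("coefficient"))
#' @rdname accessors
#' @export
setMethod("coefficient", "ThresholdModel", function(object)
  object@coefficient)

#' @rdname accessors
#' @export
setGeneric("baselines", function(object) standardGeneric("baselines"))
#' @rdname accessors
#' @export
setMethod("baselines", "ThresholdModel", function(object) object@baselines)

#' @rdname accessors
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))
#' @rdname accessors
#' @export
setMethod("thresholds", "ThresholdModel", function(object) object@thresholds)

#' @rdname accessors
#' @export
setGeneric("rocPoints", function(object) standardGeneric("rocPoints"))
#' @rdname accessors
#' @export
setMethod("rocPoints", "ThresholdModel", function(object) object@rocPoints)

setMethod("show", "MarginField", function(object) {
  cat("MarginField", object@marginId, "field", object@fieldIndex, "\n")
  cat("  ", paste(dim(object@pixels), collapse = " x "), "px grid, ",
      sum(object@circularMask), " in-field px\n", sep = "")
  cat("  tumor px: ", sum(object@truthMask),
      "; contact factor: ", signif(object@contactFactor, 3), "\n", sep = "")
})

setMethod("show", "MarginSurface", function(object) {
  cat("MarginSurface", object@marginId, sprintf("(%s, %s, patient %s)\n",
      object@orientation, object@stage, object@patientId))
  cat("  fields:", length(object@fields),
      " histology:", object@histopath@histology, "\n")
})

setMethod("show", "MarginCohort", function(object) {
  st <- vapply(object@surfaces, function(s) s@stage, character(1))
  tum <- vapply(object@surfaces, surfaceContainsTumor, logical(1))
  cat("MarginCohort:", nrow(object@patients), "patients,",
      length(object@surfaces), "margin surfaces\n")
  cat("  intermediate:", sum(st == "intermediate"),
      " final:", sum(st == "final"),
      " tumor-bearing:", sum(tum), "\n")
  cat("  image grid:", object@config@imageSizePx, "px, seed:",
      object@config@seed, "\n")
})

setMethod("show", "ThresholdModel", function(object) {
  cat("ThresholdModel\n")
  cat("  normal-tissue baseline coefficient:",
      signif(object@coefficient, 5), "\n")
  cat("  patients:", length(object@thresholds),
      " ROC points:", nrow(object@rocPoints), "\n")
})
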