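#' Create a generator configuration
#'
#' Validated constructor for [GeneratorConfig-class]. All arguments have
#' defaults describing the cohort the analysis assumes; see the class
#' documentation for the meaning and units of each field. Invalid values
#' raise a configuration error naming the offending field.
#'
#' @param nPatients,fieldsPerMargin,imageSizePx,fieldDiameterCm,tnRatioMean
#'   see [GeneratorConfig-class].
#' @param tnRatioSd,baselineMean,baselineCv,haloSigmaPx,activationHalftimeMin
#'   see [GeneratorConfig-class].
#' @param noiseCv,tumorPrevalencePerMargin,benignHotspotRate,occultTumorRate
#'   see [GeneratorConfig-class].
#' @param contactFailureRate,shortIntervalRate,doseFailureRate,hematomaRate
#'   see [GeneratorConfig-class].
#' @param dataLossRate,intervalRangeMin,tumorRadiusFracRange
#'   see [GeneratorConfig-class].
#' @param hotspotRatioRange,hotspotRadiusFracRange,occultAttenuationRange
#'   see [GeneratorConfig-class].
#' @param contactRange,contactFailureRange,initScanFields,orientations,seed
#'   see [GeneratorConfig-class].
#' @return a validated [GeneratorConfig-class] object.
#' @examples
#' cfg <- generatorConfig(nPatients = 5, imageSizePx = 48, seed = 1)
#' cfg
#' @export
generatorConfig <- function(nPatients = 40L,
                            fieldsPerMargin = 1L,
                            imageSizePx = 256L,
                            fieldDiameterCm = 2.6,
                            tnRatioMean = 3.9,
                            tnRatioSd = 0.084,
                            baselineMean = 100,
                            baselineCv = 0.2,
                            haloSigmaPx = NULL,
                            activationHalftimeMin = 5,
                            noiseCv = 0.1,
                            tumorPrevalencePerMargin = 0.03,
                            benignHotspotRate = 0.7,
                            occultTumorRate = 0.15,
                            contactFailureRate = 0.015,
                            shortIntervalRate = 0,
                            doseFailureRate = 0,
                            hematomaRate = 0,
                            dataLossRate = 0,
                            intervalRangeMin = c(110, 402),
                            tumorRadiusFracRange = c(0.08, 0.25),
                            hotspotRatioRange = c(1.6, 5.2),
                            hotspotRadiusFracRange = c(0.03, 0.08),
                            occultAttenuationRange = c(0.05, 0.7),
                            contactRange = c(0.90, 1.0),
                            contactFailureRange = c(0.45, 0.80),
                            initScanFields = 3L,
                            orientations = c("superior", "inferior",
                                             "medial", "lateral",
                                             "anterior", "posterior"),
                            seed = 1L) {
  if (is.null(haloSigmaPx)) haloSigmaPx <- imageSizePx / 42
  obj <- tryCatch(
    new("GeneratorConfig",
        nPatients = .asCount(nPatients, "nPatients"),
        fieldsPerMargin = .asCount(fieldsPerMargin, "fieldsPerMargin"),
        imageSizePx = .asCount(imageSizePx, "imageSizePx"),
        fieldDiameterCm = .asScalar(fieldDiameterCm, "fieldDiameterCm"),
        tnRatioMean = .asScalar(tnRatioMean, "tnRatioMean"),
        tnRatioSd = .asScalar(tnRatioSd, "tnRatioSd"),
        baselineMean = .asScalar(baselineMean, "baselineMean"),
        baselineCv = .asScalar(baselineCv, "baselineCv"),
        haloSigmaPx = .asScalar(haloSigmaPx, "haloSigmaPx"),
        activationHalftimeMin = .asScalar(activationHalftimeMin,
                                          "activationHalftimeMin"),
        noiseCv = .asScalar(noiseCv, "noiseCv"),
        tumorPrevalencePerMargin = .asScalar(tumorPrevalencePerMargin,
                                             "tumorPrevalencePerMargin"),
        benignHotspotRate = .asScalar(benignHotspotRate, "benignHotspotRate"),
        occultTumorRate = .asScalar(occultTumorRate, "occultTumorRate"),
        contactFailureRate = .asScalar(contactFailureRate,
                                       "contactFailureRate"),
        shortIntervalRate = .asScalar(shortIntervalRate, "shortIntervalRate"),
        doseFailureRate = .asScalar(doseFailureRate, "doseFailureRate"),
        hematomaRate = .asScalar(hematomaRate, "hematomaRate"),
        dataLossRate = .asScalar(dataLossRate, "dataLossRate"),
        intervalRangeMin = as.numeric(intervalRangeMin),
        tumorRadiusFracRange = as.numeric(tumorRadiusFracRange),
        hotspotRatioRange = as.numeric(hotspotRatioRange),
        hotspotRadiusFracRange = as.numeric(hotspotRadiusFracRange),
        occultAttenuationRange = as.numeric(occultAttenuationRange),
        contactRange = as.numeric(contactRange),
        contactFailureRange = as.numeric(contactFailureRange),
        initScanFields = .asCount(initScanFields, "initScanFields"),
        orientations = as.character(orientations),
        seed = .asCount(seed, "seed")),
    error = function(e) stop("invalid generator configuration: ",
                             conditionMessage(e), call. = FALSE))
  obj
}

#' Create a quality-control configuration
#'
#' @param minIntervalMin minimum eligible injection-to-imaging interval,
#'   minutes (default 101, the empirically established lower bound).
#' @param maxIntervalMin upper interval limit, minutes; \code{Inf} (the
#'   default) disables it -- 402 min is the longest observed acceptable
#'   interval, not a cutoff.
#' @param contactCutoff contact-score cutoff; images at or below it are
#'   excluded (default 0.84).
#' @return a validated [QcConfig-class].
#' @examples
#' qcConfig()
#' @export
qcConfig <- function(minIntervalMin = 101, maxIntervalMin = Inf,
                     contactCutoff = 0.84) {
  tryCatch(
    new("QcConfig", minIntervalMin = .asScalar(minIntervalMin,
                                               "minIntervalMin"),
        maxIntervalMin = as.numeric(maxIntervalMin)[1],
        contactCutoff = .asScalar(contactCutoff, "contactCutoff")),
    error = function(e) stop("invalid QC configuration: ",
                             conditionMessage(e), call. = FALSE))
}

#' Create a detection configuration
#'
#' @param minAreaPx minimum 8-connected suprathreshold component area, in
#'   pixels (default 9).
#' @param smoothing \code{"median3x3"} (default) or \code{"none"}.
#' @return a validated [DetectionConfig-class].
#' @examples
#' detectionConfig(minAreaPx = 1, smoothing = "none")
#' @export
detectionConfig <- function(minAreaPx = 9L, smoothing = "median3x3") {
  tryCatch(
    new("DetectionConfig", minAreaPx = .asCount(minAreaPx, "minAreaPx"),
        smoothing = as.character(smoothing)[1]),
    error = function(e) stop("invalid detection configuration: ",
                             conditionMessage(e), call. = FALSE))
}

#' Create a histopathology finding
#'
#' @param histology one of \code{IDC}, \code{ILC}, \code{IC_mixed},
#'   \code{DCIS}, \code{IDC_DCIS}, \code{benign}.
#' @param specimenKind specimen provenance; default \code{"shave"}.
#' @param distanceToInkMm distance to ink in mm (\code{NA} if unknown).
#' @param onInk whether tumor touches the inked surface.
#' @param tumorPresent whether tumor is present anywhere in the specimen;
#'   defaults to \code{TRUE} for any non-benign histology.
#' @return a validated [HistopathFinding-class].
#' @examples
#' histopathFinding("DCIS", distanceToInkMm = 1.5)
#' histopathFinding("IDC", onInk = TRUE)
#' @export
histopathFinding <- function(histology,
                             specimenKind = "shave",
                             distanceToInkMm = NA_real_,
                             onInk = FALSE,
                             tumorPresent = !identical(histology, "benign")) {
  new("HistopathFinding", specimenKind = as.character(specimenKind)[1],
      histology = as.character(histology)[1],
      distanceToInkMm = as.numeric(distanceToInkMm)[1],
      onInk = isTRUE(onInk), tumorPresent = isTRUE(tumorPresent))
}

#' Create a pipeline configuration
#'
#' @param generator a [GeneratorConfig-class] (default [generatorConfig()]).
#' @param qc a [QcConfig-class] (default [qcConfig()]).
#' @param detection a [DetectionConfig-class] (default [detectionConfig()]).
#' @param evalMode \code{"resubstitution"} or \code{"leave_one_patient_out"}.
#' @param coefficientOverride fixed coefficient bypassing calibration
#'   (\code{NA} = calibrate on the cohort).
#' @param applyQc run the QC stage (default \code{TRUE}).
#' @param writeImages write per-field TIFFs and mask PNGs from
#'   [runPipeline()] (default \code{TRUE}).
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(generator = generatorConfig(),
                           qc = qcConfig(),
                           detection = detectionConfig(),
                           evalMode = "resubstitution",
                           coefficientOverride = NA_real_,
                           applyQc = TRUE,
                           writeImages = TRUE) {
  new("PipelineConfig", generator = generator, qc = qc,
      detection = detection, evalMode = as.character(evalMode)[1],
      coefficientOverride = as.numeric(coefficientOverride)[1],
      applyQc = isTRUE(applyQc), writeImages = isTRUE(writeImages))
}

.asCount <- function(x, field) {
  v <- suppressWarnings(as.integer(x[1]))
  if (is.na(v)) stop(field, " must be a whole number", call. = FALSE)
  v
}

.asScalar <- function(x, field) {
  v <- suppressWarnings(as.numeric(x[1]))
  if (is.na(v)) stop(field, " must be a number", call. = FALSE)
  v
}
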