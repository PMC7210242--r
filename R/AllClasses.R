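#' @import methods
NULL

#' Configuration for the synthetic cavity-margin cohort generator
#'
#' Holds every tunable of the image and cohort simulator. Defaults encode the
#' study conditions the analysis assumes: a 2.6-cm circular field of view,
#' tumor-to-normal (T:N) fluorescence ratios centred on 3.9 so that
#' per-subtype means fall in the reported 3.78--4.11 band, a protease
#' activation curve that has plateaued by ~100 min after probe injection,
#' probe--tissue contact attenuation, and multiplicative lognormal pixel
#' noise.
#'
#' @slot nPatients number of patients to simulate.
#' @slot fieldsPerMargin number of 2.6-cm fields of view per margin surface.
#' @slot imageSizePx side length (pixels) of the square grid holding the
#'   circular field.
#' @slot fieldDiameterCm physical field-of-view diameter (cm).
#' @slot tnRatioMean mean of the per-specimen T:N signal ratio draw.
#' @slot tnRatioSd standard deviation of the T:N draw; the default puts
#'   ~95\% of draws inside 3.78--4.11.
#' @slot baselineMean mean normal-tissue baseline fluorescence (arbitrary
#'   fluorescence units, AFU; the absolute scale is arbitrary).
#' @slot baselineCv between-patient coefficient of variation of the baseline.
#' @slot haloSigmaPx Gaussian sigma (pixels) of the signal halo extending
#'   beyond the tumor border.
#' @slot activationHalftimeMin halftime (min) of the saturating activation
#'   curve \code{A(t) = t / (t + halftime)}.
#' @slot noiseCv coefficient of variation of multiplicative pixel noise.
#' @slot tumorPrevalencePerMargin probability a margin surface contains tumor.
#' @slot benignHotspotRate probability a surface carries a benign focus of
#'   elevated signal (the false-positive source).
#' @slot occultTumorRate probability a tumor-bearing surface exposes only an
#'   attenuated fraction of its signal at the cavity wall (sub-threshold
#'   tumor, the false-negative source).
#' @slot contactFailureRate probability a field is imaged with poor
#'   probe--tissue contact (contact factor drawn below the QC cutoff).
#' @slot shortIntervalRate,doseFailureRate,hematomaRate,dataLossRate
#'   per-patient probabilities of the patient-level exclusion events.
#' @slot intervalRangeMin range (min) from which eligible injection-to-imaging
#'   intervals are drawn uniformly.
#' @slot tumorRadiusFracRange tumor disc radius range, as a fraction of the
#'   field diameter.
#' @slot hotspotRatioRange intensity range (multiples of baseline) of benign
#'   hotspots.
#' @slot hotspotRadiusFracRange benign hotspot radius range (fraction of field
#'   diameter); hotspots are small, halo-free foci.
#' @slot occultAttenuationRange range of the signal fraction exposed by an
#'   occult tumor.
#' @slot contactRange contact-factor range of well-seated fields.
#' @slot contactFailureRange contact-factor range of failed fields.
#' @slot initScanFields number of tumor-free initialisation-scan fields used
#'   to estimate the per-patient normal-tissue baseline.
#' @slot orientations cavity wall orientation labels.
#' @slot seed integer seed; together with the configuration it fully
#'   determines the generated cohort.
#'
#' @seealso [generatorConfig()] for the validated constructor,
#'   [generateCohort()] for the generator itself.
#' @export
setClass("GeneratorConfig",
  representation(
    nPatients = "integer",
    fieldsPerMargin = "integer",
    imageSizePx = "integer",
    fieldDiameterCm = "numeric",
    tnRatioMean = "numeric",
    tnRatioSd = "numeric",
    baselineMean = "numeric",
    baselineCv = "numeric",
    haloSigmaPx = "numeric",
    activationHalftimeMin = "numeric",
    noiseCv = "numeric",
    tumorPrevalencePerMargin = "numeric",
    benignHotspotRate = "numeric",
    occultTumorRate = "numeric",
    contactFailureRate = "numeric",
    shortIntervalRate = "numeric",
    doseFailureRate = "numeric",
    hematomaRate = "numeric",
    dataLossRate = "numeric",
    intervalRangeMin = "numeric",
    tumorRadiusFracRange = "numeric",
    hotspotRatioRange = "numeric",
    hotspotRadiusFracRange = "numeric",
    occultAttenuationRange = "numeric",
    contactRange = "numeric",
    contactFailureRange = "numeric",
    initScanFields = "integer",
    orientations = "character",
    seed = "integer"
  )
)

setValidity("GeneratorConfig", function(object) {
  msgs <- character()
  rates <- c(
    tumorPrevalencePerMargin = object@tumorPrevalencePerMargin,
    benignHotspotRate = object@benignHotspotRate,
    occultTumorRate = object@occultTumorRate,
    contactFailureRate = object@contactFailureRate,
    shortIntervalRate = object@shortIntervalRate,
    doseFailureRate = object@doseFailureRate,
    hematomaRate = object@hematomaRate,
    dataLossRate = object@dataLossRate
  )
  bad <- names(rates)[is.na(rates) | rates < 0 | rates > 1]
  if (length(bad))
    msgs <- c(msgs, paste0("rate fields must lie in [0, 1]: ",
                           paste(bad, collapse = ", ")))
  if (object@tnRatioMean <= 1)
    msgs <- c(msgs, "tnRatioMean must exceed 1")
  if (object@imageSizePx < 32L)
    msgs <- c(msgs, "imageSizePx must be at least 32")
  if (object@nPatients < 1L)
    msgs <- c(msgs, "nPatients must be at least 1")
  if (object@fieldsPerMargin < 1L)
    msgs <- c(msgs, "fieldsPerMargin must be at least 1")
  if (object@baselineMean <= 0)
    msgs <- c(msgs, "baselineMean must be positive")
  if (object@activationHalftimeMin <= 0)
    msgs <- c(msgs, "activationHalftimeMin must be positive")
  for (rng in c("intervalRangeMin", "tumorRadiusFracRange",
                "hotspotRatioRange", "hotspotRadiusFracRange",
                "occultAttenuationRange", "contactRange",
                "contactFailureRange")) {
    v <- slot(object, rng)
    if (length(v) != 2L || any(is.na(v)) || v[1] > v[2])
      msgs <- c(msgs, paste0(rng, " must be a non-decreasing length-2 range"))
  }
  if (slot(object, "intervalRangeMin")[1] <= 0)
    msgs <- c(msgs, "intervalRangeMin must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Quality-control configuration
#'
#' Eligibility rules applied before threshold calibration: the minimum
#' injection-to-imaging interval (probe activation must have plateaued;
#' 101 min is the empirically established lower bound) and the probe-contact
#' cutoff (an in-vivo/ex-vivo signal ratio at or below 0.84 indicates poor
#' probe--tissue contact). No upper interval limit is enforced by default:
#' signal remained acceptable at the longest observed interval (402 min).
#'
#' @slot minIntervalMin minimum eligible injection-to-imaging interval (min).
#' @slot maxIntervalMin upper interval limit (min); \code{Inf} disables it.
#' @slot contactCutoff images with contact score \code{<=} this value are
#'   excluded.
#' @export
setClass("QcConfig",
  representation(minIntervalMin = "numeric", maxIntervalMin = "numeric",
                 contactCutoff = "numeric"))

setValidity("QcConfig", function(object) {
  msgs <- character()
  if (object@minIntervalMin <= 0)
    msgs <- c(msgs, "minIntervalMin must be positive")
  if (object@contactCutoff <= 0 || object@contactCutoff > 1)
    msgs <- c(msgs, "contactCutoff must lie in (0, 1]")
  if (object@maxIntervalMin <= object@minIntervalMin)
    msgs <- c(msgs, "maxIntervalMin must exceed minIntervalMin")
  if (length(msgs)) msgs else TRUE
})

#' Detection configuration
#'
#' How a field of view is called positive: pixels are smoothed with an exact
#' 3x3 median filter, compared strictly against the patient's threshold, and
#' the image is positive when the largest 8-connected suprathreshold
#' component reaches \code{minAreaPx} pixels (a speckle guard; the clinical
#' rule is "any area of signal above threshold").
#'
#' @slot minAreaPx minimum connected suprathreshold area, in pixels.
#' @slot smoothing \code{"median3x3"} or \code{"none"}.
#' @export
setClass("DetectionConfig",
  representation(minAreaPx = "integer", smoothing = "character"))

setValidity("DetectionConfig", function(object) {
  msgs <- character()
  if (object@minAreaPx < 1L)
    msgs <- c(msgs, "minAreaPx must be at least 1")
  if (!object@smoothing %in% c("median3x3", "none"))
    msgs <- c(msgs, "smoothing must be 'median3x3' or 'none'")
  if (length(msgs)) msgs else TRUE
})

#' A histopathology finding for one margin specimen
#'
#' @slot specimenKind one of \code{main_specimen_surface}, \code{shave},
#'   \code{therapeutic_shave}, \code{re_excision}.
#' @slot histology one of \code{IDC}, \code{ILC}, \code{IC_mixed},
#'   \code{DCIS}, \code{IDC_DCIS} (mixed invasive + in-situ components),
#'   \code{benign}.
#' @slot distanceToInkMm distance from tumor to the inked surface (mm);
#'   \code{NA} when unknown or irrelevant (benign).
#' @slot onInk \code{TRUE} when tumor cells touch the inked surface.
#' @slot tumorPresent \code{TRUE} when any tumor is present anywhere in the
#'   specimen (the sense used when a shave serves as ground truth).
#' @export
setClass("HistopathFinding",
  representation(specimenKind = "character", histology = "character",
                 distanceToInkMm = "numeric", onInk = "logical",
                 tumorPresent = "logical"))

.HISTOLOGIES <- c("IDC", "ILC", "IC_mixed", "DCIS", "IDC_DCIS", "benign")
.SPECIMEN_KINDS <- c("main_specimen_surface", "shave", "therapeutic_shave",
                     "re_excision")

setValidity("HistopathFinding", function(object) {
  msgs <- character()
  if (!object@histology %in% .HISTOLOGIES)
    msgs <- c(msgs, paste0("histology must be one of: ",
                           paste(.HISTOLOGIES, collapse = ", ")))
  if (!object@specimenKind %in% .SPECIMEN_KINDS)
    msgs <- c(msgs, paste0("specimenKind must be one of: ",
                           paste(.SPECIMEN_KINDS, collapse = ", ")))
  if (!is.na(object@distanceToInkMm) && object@distanceToInkMm < 0)
    msgs <- c(msgs, "distanceToInkMm must be non-negative")
  if (identical(object@histology, "benign") && isTRUE(object@tumorPresent))
    msgs <- c(msgs, "a benign finding cannot have tumorPresent = TRUE")
  if (length(msgs)) msgs else TRUE
})

#' One imaged field of view on a cavity margin
#'
#' A single 2.6-cm circular field: the pixel grid in arbitrary fluorescence
#' units (AFU), the circular validity mask (pixels outside the field are
#' \code{NA}, not zero, so they cannot bias baseline statistics), the
#' ground-truth tumor mask recorded before halo convolution, the
#' probe--tissue contact factor, and the summary signal of the matched
#' ex-vivo specimen image used by the contact score.
#'
#' @slot marginId identifier of the parent margin surface.
#' @slot fieldIndex 1-based index of this field within the surface.
#' @slot pixels numeric matrix of AFU values; \code{NA} outside the circular
#'   field.
#' @slot circularMask logical matrix flagging in-field pixels.
#' @slot truthMask logical matrix flagging true tumor pixels (subset of the
#'   circular mask).
#' @slot contactFactor probe--tissue contact factor in (0, 1].
#' @slot exVivoReference summary AFU signal of the matched ex-vivo specimen.
#' @export
setClass("MarginField",
  representation(marginId = "character", fieldIndex = "integer",
                 pixels = "matrix", circularMask = "matrix",
                 truthMask = "matrix", contactFactor = "numeric",
                 exVivoReference = "numeric"))

setValidity("MarginField", function(object) {
  msgs <- character()
  d <- dim(object@pixels)
  if (!identical(d, dim(object@circularMask)) ||
      !identical(d, dim(object@truthMask)))
    msgs <- c(msgs, "pixels, circularMask and truthMask dimensions differ")
  inmask <- object@pixels[object@circularMask]
  if (any(is.na(inmask)) || any(inmask < 0))
    msgs <- c(msgs, "in-mask pixels must be non-negative and non-missing")
  if (any(object@truthMask & !object@circularMask))
    msgs <- c(msgs, "truthMask must be a subset of circularMask")
  if (is.na(object@contactFactor) || object@contactFactor <= 0 ||
      object@contactFactor > 1)
    msgs <- c(msgs, "contactFactor must lie in (0, 1]")
  if (is.na(object@exVivoReference) || object@exVivoReference <= 0)
    msgs <- c(msgs, "exVivoReference must be positive")
  if (length(msgs)) msgs else TRUE
})

#' An oriented cavity margin surface
#'
#' One cavity wall orientation (superior, inferior, ...) at one stage of the
#' operation: \emph{intermediate} surfaces are imaged after removal of the
#' main specimen but before shaved cavity margins are taken; \emph{final}
#' surfaces after comprehensive shaves. A large cavity wall may need several
#' fields of view.
#'
#' @slot marginId unique surface identifier.
#' @slot patientId parent patient identifier.
#' @slot orientation cavity wall orientation label.
#' @slot stage \code{"intermediate"} or \code{"final"}.
#' @slot fields list of [MarginField-class] objects (at least one).
#' @slot histopath the [HistopathFinding-class] for tissue excised at this
#'   site.
#' @export
setClass("MarginSurface",
  representation(marginId = "character", patientId = "character",
                 orientation = "character", stage = "character",
                 fields = "list", histopath = "HistopathFinding"))

setValidity("MarginSurface", function(object) {
  msgs <- character()
  if (!length(object@fields))
    msgs <- c(msgs, "a surface needs at least one field")
  if (!all(vapply(object@fields, is, logical(1), class2 = "MarginField")))
    msgs <- c(msgs, "fields must all be MarginField objects")
  if (!object@stage %in% c("intermediate", "final"))
    msgs <- c(msgs, "stage must be 'intermediate' or 'final'")
  if (length(msgs)) msgs else TRUE
})

#' A simulated patient cohort with imaged margin surfaces
#'
#' @slot patients data.frame with one row per patient: \code{patient_id},
#'   \code{injection_to_imaging_min}, \code{baseline_true} (latent AFU),
#'   \code{dose_ok}, \code{hematoma}, \code{data_lost}.
#' @slot surfaces list of [MarginSurface-class] objects.
#' @slot initScans named list (by patient) of tumor-free initialisation-scan
#'   [MarginField-class] objects used for baseline estimation.
#' @slot config the [GeneratorConfig-class] that produced the cohort.
#' @export
setClass("MarginCohort",
  representation(patients = "data.frame", surfaces = "list",
                 initScans = "list", config = "GeneratorConfig"))

setValidity("MarginCohort", function(object) {
  msgs <- character()
  need <- c("patient_id", "injection_to_imaging_min", "baseline_true",
            "dose_ok", "hematoma", "data_lost")
  miss <- setdiff(need, names(object@patients))
  if (length(miss))
    msgs <- c(msgs, paste0("patients is missing columns: ",
                           paste(miss, collapse = ", ")))
  if (anyDuplicated(object@patients$patient_id))
    msgs <- c(msgs, "patient_id must be unique")
  sid <- vapply(object@surfaces, function(s) s@marginId, character(1))
  if (anyDuplicated(sid))
    msgs <- c(msgs, "marginId must be unique across surfaces")
  if (length(msgs)) msgs else TRUE
})

#' Per-patient detection thresholds from a pooled baseline coefficient
#'
#' The calibrated detection rule: a single pooled normal-tissue-baseline
#' coefficient chosen on a ROC over normalized training signals, converted
#' into one unique threshold per patient by multiplying with that patient's
#' estimated normal-tissue baseline.
#'
#' @slot coefficient the pooled normal-tissue-baseline coefficient
#'   (dimensionless).
#' @slot baselines named numeric, estimated normal-tissue baseline (AFU) per
#'   patient.
#' @slot thresholds named numeric, detection threshold (AFU) per patient;
#'   always \code{coefficient * baselines}.
#' @slot rocPoints data.frame with columns \code{coefficient},
#'   \code{sensitivity}, \code{specificity}, sorted by coefficient.
#' @export
setClass("ThresholdModel",
  representation(coefficient = "numeric", baselines = "numeric",
                 thresholds = "numeric", rocPoints = "data.frame"))

setValidity("ThresholdModel", function(object) {
  msgs <- character()
  if (is.na(object@coefficient) || object@coefficient <= 0)
    msgs <- c(msgs, "coefficient must be positive")
  if (!identical(sort(names(object@baselines)), sort(names(object@thresholds))))
    msgs <- c(msgs, "baselines and thresholds must cover the same patients")
  else {
    expect <- object@coefficient * object@baselines[names(object@thresholds)]
    if (any(abs(object@thresholds - expect) >
            1e-8 * pmax(1, abs(expect))))
      msgs <- c(msgs, "thresholds must equal coefficient * baselines")
  }
  if (!all(c("coefficient", "sensitivity", "specificity") %in%
           names(object@rocPoints)))
    msgs <- c(msgs, "rocPoints needs coefficient/sensitivity/specificity")
  if (length(msgs)) msgs else TRUE
})

#' Pipeline configuration
#'
#' Bundles the stage configurations, the evaluation mode and the seed for an
#' end-to-end run: simulate, quality control, calibrate, detect, adjudicate,
#' evaluate.
#'
#' @slot generator a [GeneratorConfig-class].
#' @slot qc a [QcConfig-class].
#' @slot detection a [DetectionConfig-class].
#' @slot evalMode \code{"resubstitution"} (calibrate and classify on the same
#'   cohort, as the original study did) or \code{"leave_one_patient_out"}
#'   (each patient classified with a coefficient fit on the others).
#' @slot coefficientOverride optional fixed coefficient bypassing ROC
#'   selection (\code{NA} = calibrate).
#' @slot applyQc whether the QC stage runs (ablation switch).
#' @slot writeImages whether [runPipeline()] writes per-field TIFF/PNG files.
#' @export
setClass("PipelineConfig",
  representation(generator = "GeneratorConfig", qc = "QcConfig",
                 detection = "DetectionConfig", evalMode = "character",
                 coefficientOverride = "numeric", applyQc = "logical",
                 writeImages = "logical"))

setValidity("PipelineConfig", function(object) {
  msgs <- character()
  if (!object@evalMode %in% c("resubstitution", "leave_one_patient_out"))
    msgs <- c(msgs,
      "evalMode must be 'resubstitution' or 'leave_one_patient_out'")
  if (!is.na(object@coefficientOverride) && object@coefficientOverride <= 0)
    msgs <- c(msgs, "coefficientOverride must be positive when set")
  if (length(msgs)) msgs else TRUE
})
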