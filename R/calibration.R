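## Per-patient baseline estimation and pooled-coefficient ROC calibration.

#' Estimate a patient's normal-tissue baseline
#'
#' Pools the valid in-mask pixels of the initialisation-scan images (taken
#' over predominantly normal tissue at the start of cavity scanning) and
#' takes their median. The median is robust to occasional benign foci of
#' elevated signal within the scan.
#'
#' @param initScanImages a [MarginField-class] or list of them.
#' @param patientId optional identifier recorded on the estimate.
#' @return list with \code{patientId}, \code{baselineHat} (AFU),
#'   \code{nPixelsUsed}, \code{method}.
#' @examples
#' f <- renderField(100, 240, generatorConfig(noiseCv = 0, imageSizePx = 48))
#' estimateBaseline(f)$baselineHat  # activation x 100
#' @export
estimateBaseline <- function(initScanImages, patientId = NA_character_) {
  if (is(initScanImages, "MarginField"))
    initScanImages <- list(initScanImages)
  if (!length(initScanImages))
    stop("baseline estimation needs at least one initialisation-scan image")
  px <- unlist(lapply(initScanImages, function(f) {
    stopifnot(is(f, "MarginField"))
    f@pixels[f@circularMask]
  }), use.names = FALSE)
  list(patientId = patientId, baselineHat = stats::median(px),
       nPixelsUsed = length(px), method = "pooled_pixel_median")
}

#' Normalize a signal by the normal-tissue baseline
#'
#' @param value signal value(s), AFU.
#' @param baseline a baseline estimate from [estimateBaseline()], or a
#'   positive number (AFU).
#' @return dimensionless normalized signal.
#' @examples
#' normalizeSignal(390, 100)  # a typical tumor pixel reads ~3.9
#' @export
normalizeSignal <- function(value, baseline) {
  b <- if (is.list(baseline)) baseline$baselineHat else baseline
  if (is.na(b) || b <= 0) stop("baseline must be positive")
  value / b
}

#' Per-surface training signal
#'
#' The summary statistic entering ROC calibration for one margin surface:
#' the maximum normalized in-mask pixel after 3x3 median smoothing, taken
#' over all the surface's fields of view.
#'
#' @param surface a [MarginSurface-class].
#' @param baseline baseline estimate or positive number (AFU).
#' @param config a [DetectionConfig-class] (controls smoothing).
#' @return dimensionless summary signal.
#' @export
surfaceSignal <- function(surface, baseline, config = detectionConfig()) {
  vals <- vapply(surface@fields, function(f) {
    sm <- if (config@smoothing == "median3x3")
      medianSmooth(f@pixels, f@circularMask) else f@pixels
    max(sm[f@circularMask])
  }, numeric(1))
  normalizeSignal(max(vals), baseline)
}

#' Build a ROC over candidate baseline coefficients
#'
#' For every candidate coefficient (the sorted unique sample values) the
#' decision rule \code{value > coefficient} is evaluated at the sample
#' level: sensitivity is the fraction of tumor-bearing samples called
#' positive, specificity the fraction of tumor-free samples called
#' negative.
#'
#' @param values normalized summary signals, one per training sample.
#' @param labels logical (or 0/1) ground-truth tumor labels.
#' @return data.frame with columns \code{coefficient}, \code{sensitivity},
#'   \code{specificity}, sorted by coefficient.
#' @examples
#' buildRoc(c(1, 2), c(FALSE, TRUE))  # coefficient 1: sens 1, spec 1
#' @export
buildRoc <- function(values, labels) {
  labels <- as.logical(labels)
  if (length(values) != length(labels) || any(is.na(values)) ||
      any(is.na(labels)))
    stop("values and labels must be complete and of equal length")
  if (!any(labels) || all(labels))
    stop("ROC calibration needs both tumor-bearing and tumor-free samples")
  cand <- sort(unique(values))
  pos <- values[labels]
  neg <- values[!labels]
  sens <- vapply(cand, function(cc) mean(pos > cc), numeric(1))
  spec <- vapply(cand, function(cc) mean(neg <= cc), numeric(1))
  data.frame(coefficient = cand, sensitivity = sens, specificity = spec)
}

#' Select the operating coefficient on a ROC
#'
#' Chooses the coefficient maximizing Youden's J (sensitivity +
#' specificity - 1), the symmetric criterion for "optimizing both
#' sensitivity and specificity". Ties break toward the smaller coefficient,
#' i.e. toward higher sensitivity.
#'
#' @param rocPoints data.frame from [buildRoc()].
#' @return the selected coefficient.
#' @examples
#' roc <- data.frame(coefficient = c(0.5, 2, 4),
#'                   sensitivity = c(1, 0.9, 0.3),
#'                   specificity = c(0.2, 0.9, 1))
#' selectCoefficient(roc)  # 2
#' @export
selectCoefficient <- function(rocPoints) {
  if (!nrow(rocPoints)) stop("empty ROC")
  j <- rocPoints$sensitivity + rocPoints$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  rocPoints$coefficient[min(best)]
}

#' Fit the pooled threshold model on a cohort
#'
#' Estimates each patient's normal-tissue baseline from the
#' initialisation scans, forms one normalized training sample per margin
#' surface ([surfaceSignal()] labelled by ground-truth tumor presence),
#' builds the pooled ROC, selects the normal-tissue baseline coefficient,
#' and converts it into one unique threshold per patient:
#' \code{threshold[p] = coefficient * baseline[p]}.
#'
#' @param cohort a [MarginCohort-class] (normally after
#'   [applyExclusions()]).
#' @param detection a [DetectionConfig-class].
#' @param coefficient optional fixed coefficient bypassing ROC selection.
#' @param holdOutPatient optional patient id whose surfaces are excluded
#'   from the training samples (leave-one-patient-out calibration); the
#'   patient still receives a threshold.
#' @return a [ThresholdModel-class].
#' @export
fitThresholdModel <- function(cohort, detection = detectionConfig(),
                              coefficient = NA_real_,
                              holdOutPatient = NULL) {
  stopifnot(is(cohort, "MarginCohort"))
  pids <- cohort@patients$patient_id
  missing <- pids[!pids %in% names(cohort@initScans)]
  if (length(missing))
    stop("no initialisation scans (baseline) for patient(s): ",
         paste(missing, collapse = ", "))
  base <- vapply(pids, function(p)
    estimateBaseline(cohort@initScans[[p]], p)$baselineHat, numeric(1))
  names(base) <- pids

  samples <- .trainingSamples(cohort, base, detection)
  roc <- data.frame(coefficient = numeric(), sensitivity = numeric(),
                    specificity = numeric())
  if (is.na(coefficient)) {
    keep <- if (is.null(holdOutPatient)) rep(TRUE, nrow(samples))
    else samples$patient_id != holdOutPatient
    roc <- buildRoc(samples$value[keep], samples$truth[keep])
    coefficient <- selectCoefficient(roc)
  }
  new("ThresholdModel", coefficient = coefficient, baselines = base,
      thresholds = coefficient * base, rocPoints = roc)
}

.trainingSamples <- function(cohort, baselines, detection) {
  do.call(rbind, lapply(cohort@surfaces, function(s) {
    data.frame(margin_id = s@marginId, patient_id = s@patientId,
               stage = s@stage,
               value = surfaceSignal(s, baselines[[s@patientId]], detection),
               truth = surfaceContainsTumor(s),
               stringsAsFactors = FALSE)
  }))
}
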