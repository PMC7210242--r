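## Eligibility and quality-control filters applied before calibration.

#' Is an injection-to-imaging interval eligible?
#'
#' The detection algorithm requires probe activation to have plateaued:
#' intervals shorter than the established 101-min lower bound are excluded.
#' No upper limit applies by default (signal remained acceptable at the
#' longest observed interval, 402 min).
#'
#' @param intervalMin injection-to-imaging interval(s), minutes.
#' @param config a [QcConfig-class].
#' @return logical vector.
#' @examples
#' timepointEligible(c(56, 92, 101, 402))
#' @export
timepointEligible <- function(intervalMin, config = qcConfig()) {
  if (any(is.na(intervalMin)) || any(intervalMin <= 0))
    stop("injection-to-imaging interval must be positive")
  intervalMin >= config@minIntervalMin & intervalMin <= config@maxIntervalMin
}

#' Probe-contact score
#'
#' Ratio of the in-vivo cavity-wall signal to the signal of the matched
#' ex-vivo specimen from the same site. With good probe--tissue contact the
#' in-vivo signal contains the full tissue signal, so the ratio is ~1 or
#' greater; low ratios indicate poor contact.
#'
#' @param inVivoSignal summary in-vivo signal, AFU.
#' @param exVivoSignal summary ex-vivo signal, AFU (must be positive).
#' @return dimensionless ratio (vectorized).
#' @examples
#' contactScore(8.4, 10)   # 0.84: flagged as poor contact by default QC
#' contactScore(12, 10)    # 1.2: retained
#' @export
contactScore <- function(inVivoSignal, exVivoSignal) {
  if (any(is.na(exVivoSignal)) || any(exVivoSignal <= 0))
    stop("ex-vivo signal must be positive")
  inVivoSignal / exVivoSignal
}

#' Contact score of a rendered field
#'
#' Summary statistic is the mean in-mask pixel value, compared against the
#' field's ex-vivo reference signal.
#'
#' @param field a [MarginField-class].
#' @return dimensionless contact score.
#' @export
fieldContactScore <- function(field) {
  contactScore(mean(field@pixels[field@circularMask]), field@exVivoReference)
}

#' Apply patient- and image-level exclusions
#'
#' Patient-level rules run first: too-short injection-to-imaging interval,
#' missed probe dose, extensive necrosis/hematoma, lost imaging data. Then
#' images whose contact score is at or below the cutoff are removed; a
#' surface whose fields are all removed is dropped. Records are returned in
#' deterministic (patient, then surface) order. The filter is idempotent.
#'
#' @param cohort a [MarginCohort-class], or a patient-level \code{data.frame}
#'   with columns \code{patient_id}, \code{injection_to_imaging_min},
#'   \code{dose_ok}, \code{hematoma}, \code{data_lost}.
#' @param config a [QcConfig-class].
#' @return list with elements \code{eligible} (the filtered object) and
#'   \code{exclusions} (data.frame \code{entity_id}, \code{level},
#'   \code{reason}).
#' @examples
#' res <- applyExclusions(enrollmentScenario())
#' nrow(res$eligible)    # 40 of 45 patients retained
#' res$exclusions
#' @export
setGeneric("applyExclusions",
           function(cohort, config = qcConfig())
             standardGeneric("applyExclusions"))

# the cutoff comparison is inclusive (<= 0.84) up to floating-point slack,
# so a measured ratio of exactly 0.84 is excluded
.isPoorContact <- function(score, config = qcConfig()) {
  score <= config@contactCutoff + 1e-9
}

.patientExclusions <- function(df, config) {
  reason <- rep(NA_character_, nrow(df))
  reason[!timepointEligible(df$injection_to_imaging_min, config)] <-
    "short_interval"
  reason[is.na(reason) & !df$dose_ok] <- "dose_failure"
  reason[is.na(reason) & df$hematoma] <- "hematoma_necrosis"
  reason[is.na(reason) & df$data_lost] <- "data_lost"
  reason
}

#' @rdname applyExclusions
#' @export
setMethod("applyExclusions", "data.frame", function(cohort, config) {
  need <- c("patient_id", "injection_to_imaging_min", "dose_ok", "hematoma",
            "data_lost")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("patient table is missing columns: ", paste(miss, collapse = ", "))
  reason <- .patientExclusions(cohort, config)
  hit <- !is.na(reason)
  excl <- data.frame(entity_id = cohort$patient_id[hit],
                     level = rep("patient", sum(hit)),
                     reason = reason[hit],
                     stringsAsFactors = FALSE)
  list(eligible = cohort[is.na(reason), , drop = FALSE], exclusions = excl)
})

#' @rdname applyExclusions
#' @export
setMethod("applyExclusions", "MarginCohort", function(cohort, config) {
  pats <- cohort@patients
  reason <- .patientExclusions(pats, config)
  hit <- !is.na(reason)
  patExcl <- data.frame(entity_id = pats$patient_id[hit],
                        level = rep("patient", sum(hit)),
                        reason = reason[hit],
                        stringsAsFactors = FALSE)
  keepPat <- pats$patient_id[is.na(reason)]

  imgExcl <- data.frame(entity_id = character(), level = character(),
                        reason = character(), stringsAsFactors = FALSE)
  keptSurfaces <- list()
  for (s in cohort@surfaces) {
    if (!s@patientId %in% keepPat) next
    scores <- vapply(s@fields, fieldContactScore, numeric(1))
    bad <- .isPoorContact(scores, config)
    if (any(bad)) {
      ids <- vapply(s@fields[bad], function(f)
        paste0(f@marginId, "/", f@fieldIndex), character(1))
      imgExcl <- rbind(imgExcl,
                       data.frame(entity_id = ids, level = "image",
                                  reason = "poor_contact",
                                  stringsAsFactors = FALSE))
    }
    if (all(bad)) next
    if (any(bad)) s@fields <- s@fields[!bad]
    keptSurfaces[[length(keptSurfaces) + 1L]] <- s
  }

  out <- cohort
  out@patients <- pats[is.na(reason), , drop = FALSE]
  out@surfaces <- keptSurfaces
  out@initScans <- cohort@initScans[keepPat]
  list(eligible = out, exclusions = rbind(patExcl, imgExcl))
})

#' The study enrollment accounting scenario
#'
#' A 45-patient enrollment table reproducing the cohort accounting of the
#' feasibility study this pipeline models: two patients imaged before the
#' 101-min minimum interval (at 56 and 92 min), one who did not receive the
#' planned probe dose, one with extensive necrotic tissue and hematoma at
#' the biopsy site, and one whose intraoperative imaging data was lost --
#' leaving 40 patients for algorithm development.
#'
#' @return patient-level \code{data.frame} accepted by [applyExclusions()].
#' @export
enrollmentScenario <- function() {
  df <- data.frame(
    patient_id = sprintf("P%03d", 1:45),
    injection_to_imaging_min = 180,
    dose_ok = TRUE, hematoma = FALSE, data_lost = FALSE,
    stringsAsFactors = FALSE)
  df$injection_to_imaging_min[1] <- 56
  df$injection_to_imaging_min[2] <- 92
  df$injection_to_imaging_min[45] <- 402
  df$dose_ok[3] <- FALSE
  df$hematoma[4] <- TRUE
  df$data_lost[5] <- TRUE
  df
}
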