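## Histopathology margin status, TP/FP/TN/FN adjudication and the
## clinical-outcome logic for positive final margins.

.INVASIVE <- c("IDC", "ILC", "IC_mixed")

#' Histopathology margin status
#'
#' Margins for invasive cancers (IDC, ILC, mixed invasive) are positive if
#' tumor is present on ink. For DCIS without invasion the margin is positive
#' if DCIS lies strictly less than 2 mm from ink (2.0 mm exactly is
#' negative). Mixed invasive + DCIS findings are positive if either
#' component rule fires. Benign findings are negative.
#'
#' @param finding a [HistopathFinding-class].
#' @return \code{"positive"} or \code{"negative"}.
#' @examples
#' marginStatus(histopathFinding("IDC", onInk = TRUE))        # positive
#' marginStatus(histopathFinding("DCIS", distanceToInkMm = 1.5)) # positive
#' marginStatus(histopathFinding("DCIS", distanceToInkMm = 2))   # negative
#' @export
marginStatus <- function(finding) {
  stopifnot(is(finding, "HistopathFinding"))
  h <- finding@histology
  if (h == "benign") return("negative")
  if (h %in% .INVASIVE)
    return(if (finding@onInk) "positive" else "negative")
  # DCIS component present (pure DCIS or mixed IDC+DCIS)
  if (finding@onInk) return("positive")
  if (is.na(finding@distanceToInkMm))
    stop("distance to ink is required for a ", h, " finding not on ink")
  if (h == "IDC_DCIS" || h == "DCIS") {
    if (finding@distanceToInkMm < 2) return("positive")
    return("negative")
  }
  stop("unhandled histology: ", h)
}

#' Adjudicate a device reading against histopathology
#'
#' Ground truth is arbitrated in favour of the shaved specimen: when a shave
#' (or therapeutic shave) was taken at the imaged site, the site is
#' tumor-positive if tumor was found anywhere in that specimen. When no
#' specimen was taken, histopathology of the outer surface of the main
#' specimen excised from that orientation decides, via [marginStatus()].
#'
#' @param deviceReading \code{"positive"} or \code{"negative"}.
#' @param shave the shave [HistopathFinding-class], or \code{NULL} if no
#'   specimen was taken at the site.
#' @param specimenSurface the main-specimen surface
#'   [HistopathFinding-class] (always available).
#' @return one of \code{"TP"}, \code{"FP"}, \code{"TN"}, \code{"FN"}.
#' @examples
#' adjudicateReading("positive",
#'   shave = histopathFinding("IDC", distanceToInkMm = 3),
#'   specimenSurface = histopathFinding("benign"))  # TP: tumor in the shave
#' @export
adjudicateReading <- function(deviceReading, shave = NULL, specimenSurface) {
  deviceReading <- match.arg(deviceReading, c("positive", "negative"))
  truthPositive <- if (!is.null(shave)) {
    stopifnot(is(shave, "HistopathFinding"))
    shave@tumorPresent
  } else {
    marginStatus(specimenSurface) == "positive"
  }
  if (deviceReading == "positive") {
    if (truthPositive) "TP" else "FP"
  } else {
    if (truthPositive) "FN" else "TN"
  }
}

#' Clinical outcome of one positive final margin
#'
#' Surgeon-action logic for patients with positive margins after standard
#' surgery: if additional tissue was excised intraoperatively at the site of
#' device signal, the patient was spared a second surgery; a device-positive
#' site left unexcised required reoperation; a device-negative reading with
#' benign re-excision histology means the device correctly predicted that no
#' additional tumor would be found.
#'
#' @param deviceReading \code{"positive"} or \code{"negative"}.
#' @param excisedIntraop whether additional tissue was excised during the
#'   initial procedure at the site of device signal.
#' @param reExcisionTumor whether tumor was found at the (intraoperative or
#'   later) re-excision; \code{NA} when no further tissue was ever taken.
#' @return one of \code{"spared_reoperation"}, \code{"reoperation_required"},
#'   \code{"correctly_predicted_clear"}, \code{"no_action_needed"}.
#' @export
clinicalOutcome <- function(deviceReading, excisedIntraop,
                            reExcisionTumor = NA) {
  deviceReading <- match.arg(deviceReading, c("positive", "negative"))
  if (isTRUE(excisedIntraop)) {
    if (deviceReading != "positive")
      stop("inconsistent flags: intraoperative excision at a site of ",
           "device signal requires a positive reading")
    return("spared_reoperation")
  }
  if (deviceReading == "positive") return("reoperation_required")
  if (is.na(reExcisionTumor)) return("no_action_needed")
  if (reExcisionTumor) "reoperation_required" else "correctly_predicted_clear"
}

#' Clinical outcomes for a positive-final-margin table
#'
#' Vectorized [clinicalOutcome()] over a table shaped like
#' [finalMarginTable()].
#'
#' @param table data.frame with columns \code{device_reading},
#'   \code{excised_intraoperatively}, \code{tumor_found_additional}.
#' @return the table with an \code{outcome} column appended.
#' @export
clinicalOutcomes <- function(table) {
  need <- c("device_reading", "excised_intraoperatively",
            "tumor_found_additional")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("outcome table is missing columns: ", paste(miss, collapse = ", "))
  table$outcome <- vapply(seq_len(nrow(table)), function(i)
    clinicalOutcome(table$device_reading[i],
                    table$excised_intraoperatively[i],
                    table$tumor_found_additional[i]), character(1))
  table
}
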