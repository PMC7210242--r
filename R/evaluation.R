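## Cohort-level performance, T:N ratio estimation, end-to-end evaluation
## and the concordance report against the printed clinical accounting.

#' Confusion-matrix performance summary
#'
#' Sensitivity = TP / (TP + FN) and specificity = TN / (TN + FP), overall
#' and per stage, computed in exact arithmetic. Undefined rates (zero
#' denominator) are reported as \code{NA}, never silently 0 or 1.
#'
#' @param assessments data.frame with a \code{call} column (TP/FP/TN/FN)
#'   and optionally a \code{stage} column.
#' @return list with \code{counts} (named TP/FP/TN/FN), \code{sensitivity},
#'   \code{specificity}, \code{n}, and \code{perStage} (a data.frame) when
#'   stages are present.
#' @examples
#' performanceSummary(data.frame(call = c("TP", "TP", "FN", "TN", "FP")))
#' @export
performanceSummary <- function(assessments) {
  stopifnot("call" %in% names(assessments))
  bad <- setdiff(unique(assessments$call), c("TP", "FP", "TN", "FN"))
  if (length(bad)) stop("unknown calls: ", paste(bad, collapse = ", "))
  one <- function(calls) {
    n <- c(TP = sum(calls == "TP"), FP = sum(calls == "FP"),
           TN = sum(calls == "TN"), FN = sum(calls == "FN"))
    sens <- if (n[["TP"]] + n[["FN"]] > 0)
      n[["TP"]] / (n[["TP"]] + n[["FN"]]) else NA_real_
    spec <- if (n[["TN"]] + n[["FP"]] > 0)
      n[["TN"]] / (n[["TN"]] + n[["FP"]]) else NA_real_
    list(counts = n, sensitivity = sens, specificity = spec,
         n = length(calls))
  }
  out <- one(assessments$call)
  if ("stage" %in% names(assessments)) {
    st <- lapply(split(assessments$call, assessments$stage), one)
    out$perStage <- data.frame(
      stage = names(st),
      n = vapply(st, `[[`, numeric(1), "n"),
      sensitivity = vapply(st, `[[`, numeric(1), "sensitivity"),
      specificity = vapply(st, `[[`, numeric(1), "specificity"),
      row.names = NULL)
  }
  out
}

#' Estimate the tumor-to-normal signal ratio on transected specimens
#'
#' Per specimen the ratio of the mean tumor-region signal to the mean
#' normal-region signal; the estimate is the average across specimens.
#'
#' @param specimens list of specimens from
#'   [generateTransectedSpecimens()]/[renderTransectedSpecimen()] (each a
#'   list with \code{field} and \code{normalMask}).
#' @param subtype optional histology label carried on the estimate.
#' @return list with \code{subtype}, \code{ratioHat}, \code{nSpecimens},
#'   \code{perSpecimen}.
#' @export
estimateTnRatio <- function(specimens, subtype = "all") {
  if (!length(specimens)) stop("no specimens supplied")
  per <- vapply(specimens, function(sp) {
    f <- sp$field
    if (!any(f@truthMask) || !any(sp$normalMask))
      stop("each specimen needs both a tumor and a normal region")
    mean(f@pixels[f@truthMask]) / mean(f@pixels[sp$normalMask])
  }, numeric(1))
  list(subtype = subtype, ratioHat = mean(per), nSpecimens = length(per),
       perSpecimen = per)
}

#' Evaluate a synthetic cohort end to end
#'
#' Runs quality control, baseline estimation, pooled-coefficient
#' calibration, per-field classification, margin aggregation and
#' adjudication against the planted ground truth, and summarises
#' performance.
#'
#' In \code{"resubstitution"} mode (what the original development cohort
#' did) the coefficient is selected on all eligible surfaces and reapplied
#' to them. In \code{"leave_one_patient_out"} mode each patient is
#' classified with a coefficient selected on the other patients only,
#' giving an (approximately unbiased) held-out performance estimate.
#'
#' @param cohort a [MarginCohort-class].
#' @param qc a [QcConfig-class].
#' @param detection a [DetectionConfig-class].
#' @param evalMode \code{"resubstitution"} or \code{"leave_one_patient_out"}.
#' @param applyQc run the QC stage (ablation switch).
#' @param coefficient optional fixed coefficient bypassing calibration.
#' @return list with \code{report} (cohort summary incl. sensitivity and
#'   specificity), \code{assessments} (one row per adjudicated surface),
#'   \code{model} (the resubstitution [ThresholdModel-class]),
#'   \code{exclusions}.
#' @export
evaluateCohort <- function(cohort, qc = qcConfig(),
                           detection = detectionConfig(),
                           evalMode = c("resubstitution",
                                        "leave_one_patient_out"),
                           applyQc = TRUE, coefficient = NA_real_) {
  evalMode <- match.arg(evalMode)
  nEnrolled <- nrow(cohort@patients)
  exclusions <- data.frame(entity_id = character(), level = character(),
                           reason = character(), stringsAsFactors = FALSE)
  if (applyQc) {
    res <- applyExclusions(cohort, qc)
    cohort <- res$eligible
    exclusions <- res$exclusions
  }
  if (!length(cohort@surfaces)) stop("no eligible surfaces after QC")

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
    if (any(samples$truth) && any(!samples$truth)) {
      roc <- buildRoc(samples$value, samples$truth)
      coefficient <- selectCoefficient(roc)
    } else if (!any(samples$truth)) {
      # nothing to calibrate against: a conservative threshold above every
      # observed normal signal; sensitivity is undefined on such a cohort
      coefficient <- max(samples$value) * 1.01
    } else {
      coefficient <- min(samples$value) * 0.99
    }
  }
  model <- new("ThresholdModel", coefficient = coefficient,
               baselines = base, thresholds = coefficient * base,
               rocPoints = roc)

  patientCoef <- stats::setNames(rep(coefficient, length(base)),
                                 names(base))
  if (evalMode == "leave_one_patient_out" && length(base) > 1L &&
      nrow(roc)) {
    for (p in names(base)) {
      keep <- samples$patient_id != p
      if (any(samples$truth[keep]) && any(!samples$truth[keep])) {
        rocHeld <- buildRoc(samples$value[keep], samples$truth[keep])
        patientCoef[[p]] <- selectCoefficient(rocHeld)
      }
    }
  }

  rows <- lapply(cohort@surfaces, function(s) {
    thr <- patientCoef[[s@patientId]] * base[[s@patientId]]
    results <- lapply(s@fields, classifyImage, threshold = thr,
                      config = detection, baseline = base[[s@patientId]])
    reading <- aggregateMargin(results)
    call <- adjudicateReading(reading, shave = s@histopath,
                              specimenSurface = s@histopath)
    data.frame(margin_id = s@marginId, patient_id = s@patientId,
               stage = s@stage, orientation = s@orientation,
               truth = surfaceContainsTumor(s), device = reading,
               call = call,
               max_normalized_signal = max(vapply(results, function(r)
                 r@maxNormalizedSignal, numeric(1))),
               threshold_afu = thr, stringsAsFactors = FALSE)
  })
  assessments <- do.call(rbind, rows)

  perf <- performanceSummary(assessments)
  report <- list(
    n_patients_enrolled = nEnrolled,
    n_patients_analyzed = nrow(cohort@patients),
    n_surfaces_total = nrow(assessments),
    n_intermediate = sum(assessments$stage == "intermediate"),
    n_final = sum(assessments$stage == "final"),
    n_tumor_surfaces = sum(assessments$truth),
    eval_mode = evalMode,
    coefficient = model@coefficient,
    sensitivity = perf$sensitivity,
    specificity = perf$specificity,
    per_stage = perf$perStage,
    confusion = as.list(perf$counts),
    n_exclusions = nrow(exclusions))
  list(report = report, assessments = assessments, model = model,
       exclusions = exclusions)
}

#' Concordance report against the printed clinical accounting
#'
#' Recomputes, from the packaged fixture tables and the pipeline's own
#' rules, every desk-checkable quantity of the feasibility cohort: row
#' counts and device-negative readings of the intermediate-margin table,
#' final-margin sensitivity, the clinical-outcome counts, the enrollment
#' accounting (45 enrolled, 5 excluded, 40 analyzed), and the
#' interval-eligibility boundary cases.
#'
#' @return data.frame with columns \code{check}, \code{value},
#'   \code{expected}, \code{pass}.
#' @examples
#' concordanceReport()
#' @export
concordanceReport <- function() {
  t2 <- intermediateMarginTable()
  t3 <- finalMarginTable()

  # final margins: truth from additional-tissue histology, device reading
  calls <- vapply(seq_len(nrow(t3)), function(i)
    adjudicateReading(t3$device_reading[i],
                      shave = histopathFinding(
                        t3$additional_histology[i],
                        specimenKind = if (t3$excised_intraoperatively[i])
                          "therapeutic_shave" else "re_excision",
                        tumorPresent = t3$additional_histology[i] != "benign"),
                      specimenSurface = rowFinding(t3[i, ],
                        "main_specimen_surface")), character(1))
  perfFinal <- performanceSummary(data.frame(call = calls))
  outcomes <- clinicalOutcomes(t3)$outcome

  enr <- applyExclusions(enrollmentScenario())
  shortIntervals <- sum(!timepointEligible(c(56, 92, 101, 402)))

  rows <- list(
    list("intermediate_table_rows", nrow(t2), 9),
    list("intermediate_device_negative", sum(t2$device_reading == "negative"),
         3),
    list("final_table_rows", nrow(t3), 8),
    list("final_margin_sensitivity_pct", 100 * perfFinal$sensitivity, 100),
    list("final_tumor_found_rows", sum(t3$tumor_found_additional), 4),
    list("spared_reoperation", sum(outcomes == "spared_reoperation"), 2),
    list("reoperation_required", sum(outcomes == "reoperation_required"), 4),
    list("correctly_predicted_clear",
         sum(outcomes == "correctly_predicted_clear"), 2),
    list("spared_reoperation_pct",
         100 * sum(outcomes == "spared_reoperation") / nrow(t3), 25),
    list("patients_enrolled", 45, 45),
    list("patients_excluded", nrow(enr$exclusions), 5),
    list("patients_analyzed", nrow(enr$eligible), 40),
    list("short_interval_timepoints_excluded", shortIntervals, 2))

  df <- data.frame(
    check = vapply(rows, function(r) r[[1]], character(1)),
    value = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    expected = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)))
  df$pass <- df$value == df$expected
  df
}
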