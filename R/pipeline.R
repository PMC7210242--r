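## End-to-end orchestration: simulate -> qc -> calibrate -> detect ->
## adjudicate -> evaluate, with all artifacts written under a run directory.

.configAsList <- function(x) {
  sl <- methods::slotNames(class(x))
  out <- lapply(sl, function(s) {
    v <- methods::slot(x, s)
    if (isVirtualClass(class(v)) || is(v, "GeneratorConfig") ||
        is(v, "QcConfig") || is(v, "DetectionConfig"))
      .configAsList(v) else v
  })
  names(out) <- sl
  out
}

#' Run the full pipeline
#'
#' Generates the synthetic cohort, applies quality control, calibrates the
#' per-patient thresholds, classifies and adjudicates every margin surface,
#' and writes all artifacts under \code{outDir}: the resolved configuration
#' (with seed), the cohort manifest, the exclusion report, the threshold
#' model, per-surface assessments, the cohort report, and (optionally) the
#' per-field TIFF images with mask sidecars. Rerunning with the same
#' configuration reproduces the report bit for bit.
#'
#' @param config a [PipelineConfig-class].
#' @param outDir run directory (created if needed).
#' @return the evaluation list of [evaluateCohort()], invisibly, with the
#'   run directory attached as \code{runDir}.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
  stopifnot(is(config, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.configAsList(config),
                       file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  cohort <- generateCohort(config@generator)
  writeManifest(cohortManifest(cohort), file.path(outDir, "manifest.csv"))

  if (config@writeImages) {
    imgDir <- file.path(outDir, "images")
    dir.create(imgDir, showWarnings = FALSE)
    iv <- stats::setNames(cohort@patients$injection_to_imaging_min,
                          cohort@patients$patient_id)
    for (s in surfaces(cohort)) for (f in fields(s)) {
      writeFieldImage(f, file.path(imgDir,
        sprintf("%s_f%02d.tiff", s@marginId, f@fieldIndex)),
        meta = list(patient_id = s@patientId, stage = s@stage,
                    injection_to_imaging_min = iv[[s@patientId]]))
    }
  }

  res <- evaluateCohort(cohort, qc = config@qc,
                        detection = config@detection,
                        evalMode = config@evalMode,
                        applyQc = config@applyQc,
                        coefficient = config@coefficientOverride)

  utils::write.csv(res$exclusions, file.path(outDir, "exclusions.csv"),
                   row.names = FALSE)
  writeThresholdModel(res$model, file.path(outDir, "threshold_model.json"))
  utils::write.csv(res$assessments, file.path(outDir, "assessments.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  res$runDir <- outDir
  invisible(res)
}
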