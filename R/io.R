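## File formats: 16-bit grayscale TIFF fields, 8-bit PNG masks and
## overlays, CSV manifests, JSON threshold models and reports.

#' Write a field of view as 16-bit grayscale TIFF with a JSON sidecar
#'
#' Pixel values are scaled by the recorded \code{max_afu} into [0, 1] before
#' 16-bit quantization; invalid (outside-field) pixels are written as zero
#' but remain identifiable from the circular mask. The sidecar carries the
#' identifiers, contact factor and scale needed to restore AFU values, plus
#' the truth-mask path.
#'
#' @param field a [MarginField-class].
#' @param path output TIFF path; the sidecar is \code{<path>.json} and the
#'   truth mask \code{<path>_truth.png}.
#' @param meta named list of extra sidecar entries (e.g. patient_id, stage).
#' @return invisibly, the sidecar path.
#' @export
writeFieldImage <- function(field, path, meta = list()) {
  maxAfu <- max(field@pixels[field@circularMask])
  m <- field@pixels / maxAfu
  m[!field@circularMask] <- 0
  m <- pmin(pmax(m, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  truthPath <- paste0(sub("\\.tiff?$", "", path), "_truth.png")
  png::writePNG(matrix(as.numeric(field@truthMask), nrow(field@truthMask)),
                truthPath)
  sidecar <- c(list(margin_id = field@marginId,
                    field_index = field@fieldIndex,
                    contact_factor = field@contactFactor,
                    ex_vivo_reference = field@exVivoReference,
                    max_afu = maxAfu,
                    truth_mask = basename(truthPath)), meta)
  scPath <- paste0(path, ".json")
  jsonlite::write_json(sidecar, scPath, auto_unbox = TRUE, digits = NA)
  invisible(scPath)
}

#' Read a field of view written by [writeFieldImage()]
#'
#' @param path TIFF path (sidecar and truth mask are located next to it).
#' @return a [MarginField-class] (AFU values quantized to 16 bits).
#' @export
readFieldImage <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  m <- tryCatch(suppressWarnings(tiff::readTIFF(path)),
                error = function(e)
                  stop("failed to parse TIFF '", path, "': ",
                       conditionMessage(e), call. = FALSE))
  if (is.null(dim(m)) || length(dim(m)) != 2L)
    stop("failed to parse TIFF '", path, "': not a 2-D grayscale image")
  scPath <- paste0(path, ".json")
  if (!file.exists(scPath)) stop("missing sidecar: ", scPath)
  sc <- jsonlite::read_json(scPath, simplifyVector = TRUE)
  truth <- png::readPNG(file.path(dirname(path), sc$truth_mask)) > 0.5
  fov <- circularFieldMask(nrow(m))
  px <- m * sc$max_afu
  px[!fov] <- NA_real_
  new("MarginField", marginId = sc$margin_id,
      fieldIndex = as.integer(sc$field_index), pixels = px,
      circularMask = fov, truthMask = truth & fov,
      contactFactor = sc$contact_factor,
      exVivoReference = sc$ex_vivo_reference)
}

#' Cohort manifest: one row per field of view
#'
#' @param cohort a [MarginCohort-class].
#' @return data.frame with margin, patient, stage, orientation, field
#'   index, contact factor and injection-to-imaging interval.
#' @export
cohortManifest <- function(cohort) {
  iv <- stats::setNames(cohort@patients$injection_to_imaging_min,
                        cohort@patients$patient_id)
  do.call(rbind, lapply(cohort@surfaces, function(s)
    do.call(rbind, lapply(s@fields, function(f)
      data.frame(margin_id = s@marginId, patient_id = s@patientId,
                 stage = s@stage, orientation = s@orientation,
                 field_index = f@fieldIndex,
                 contact_factor = f@contactFactor,
                 injection_to_imaging_min = iv[[s@patientId]],
                 contains_tumor = any(f@truthMask),
                 stringsAsFactors = FALSE)))))
}

#' Write / read a manifest CSV
#'
#' @param manifest data.frame from [cohortManifest()].
#' @param path CSV path.
#' @return [readManifest()] returns the data.frame; writing returns the
#'   path invisibly. Round-trips are value-identical.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a threshold model as JSON
#'
#' Serializes the pooled coefficient, per-patient baselines and thresholds
#' and the ROC points at full precision; \code{read(write(x))} restores the
#' model exactly.
#'
#' @param model a [ThresholdModel-class].
#' @param path JSON path.
#' @return [readThresholdModel()] returns the model; writing returns the
#'   path invisibly.
#' @export
writeThresholdModel <- function(model, path) {
  obj <- list(coefficient = model@coefficient,
              baselines = as.list(model@baselines),
              thresholds = as.list(model@thresholds),
              roc_points = model@rocPoints)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeThresholdModel
#' @export
readThresholdModel <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roc <- as.data.frame(obj$roc_points)
  if (!nrow(roc))
    roc <- data.frame(coefficient = numeric(), sensitivity = numeric(),
                      specificity = numeric())
  new("ThresholdModel", coefficient = obj$coefficient,
      baselines = unlist(obj$baselines),
      thresholds = unlist(obj$thresholds),
      rocPoints = roc)
}
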