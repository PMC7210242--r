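## Packaged clinical reading tables from the feasibility cohort: device
## readings at histopathology-positive intermediate margins, and
## device-versus-histopathology assessment of the 8 positive final margins.

.readFixture <- function(name, expectRows) {
  path <- system.file("extdata", name, package = "fluorMargin")
  if (!nzchar(path)) stop("packaged fixture not found: ", name)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) != expectRows)
    stop("fixture ", name, " has ", nrow(df), " rows, expected ",
         expectRows)
  df
}

#' Device readings at the 9 histopathology-positive intermediate margins
#'
#' One row per tumor-containing intermediate cavity margin in the
#' feasibility cohort: the histology of the shaved cavity margin (with its
#' distance-to-ink class) and the in-vivo device reading of the cavity wall
#' at that site. Three of the nine readings were below threshold.
#'
#' @return data.frame with 9 rows; columns \code{row_id},
#'   \code{printed_histology}, \code{histology}, \code{distance_class},
#'   \code{distance_mm}, \code{on_ink}, \code{device_reading}.
#' @examples
#' table(intermediateMarginTable()$device_reading)
#' @export
intermediateMarginTable <- function() {
  .readFixture("intermediate_margin_readings.csv", 9L)
}

#' Device versus histopathology at the 8 positive final margins
#'
#' One row per patient with a positive final margin after standard surgery:
#' histopathology at the final surface of the excised standard-of-care
#' specimen, the in-vivo device reading of the corresponding cavity wall,
#' whether tumor was found in additional cavity-wall tissue taken at that
#' site, the histology of that additional tissue, and whether the surgeon
#' excised the additional margin during the initial procedure (for the six
#' patients where not, the additional-tissue result comes from a later
#' re-excision).
#'
#' @return data.frame with 8 rows; columns as in
#'   [intermediateMarginTable()] plus \code{tumor_found_additional},
#'   \code{additional_histology}, \code{excised_intraoperatively}.
#' @examples
#' clinicalOutcomes(finalMarginTable())$outcome
#' @export
finalMarginTable <- function() {
  .readFixture("final_margin_readings.csv", 8L)
}

#' Convert a fixture table row into a histopathology finding
#'
#' @param row one-row data.frame from [intermediateMarginTable()] or
#'   [finalMarginTable()].
#' @param specimenKind specimen provenance for the finding.
#' @return a [HistopathFinding-class].
#' @export
rowFinding <- function(row, specimenKind = "shave") {
  histopathFinding(row$histology, specimenKind = specimenKind,
                   distanceToInkMm = row$distance_mm,
                   onInk = isTRUE(row$on_ink),
                   tumorPresent = row$histology != "benign")
}
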