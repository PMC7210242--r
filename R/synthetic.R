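## Synthetic cohort generation: patients, margin surfaces and rendered
## fluorescence fields with known ground truth.

#' Fractional probe activation at a given injection-to-imaging interval
#'
#' Phenomenological saturating activation curve
#' \code{A(t) = t / (t + halftime)}, scaled to 1 at plateau. The default
#' halftime (5 min) puts the curve above 0.95 of plateau at the 101-min
#' eligibility bound, consistent with signal having plateaued by the time
#' imaging is allowed to start.
#'
#' @param tMin injection-to-imaging interval, minutes (vectorized).
#' @param halftimeMin activation halftime, minutes.
#' @return activation fraction in [0, 1).
#' @examples
#' activationFraction(101) >= 0.95
#' @export
activationFraction <- function(tMin, halftimeMin = 5) {
  if (any(tMin <= 0)) stop("injection-to-imaging interval must be positive")
  tMin / (tMin + halftimeMin)
}

#' Render one fluorescence field of view
#'
#' Pixel model: \code{S(x) = A(t) * c * B * [1 + (Reff - 1) * K(x)] *
#' (1 + eps(x))}, where \code{B} is the patient's latent normal-tissue
#' baseline, \code{c} the probe--tissue contact factor, \code{A(t)} the
#' activation fraction, \code{K(x)} the tumor indicator extended by a
#' Gaussian halo (so signal exceeds baseline outside the tumor border), and
#' \code{(1 + eps)} multiplicative lognormal noise with unit mean. For an
#' occult tumor the effective ratio is \code{Reff = 1 + (R - 1) * exposure}
#' with \code{exposure < 1}. Benign hotspots are small halo-free discs whose
#' relative intensity competes with the tumor factor by pixelwise maximum.
#' The ground-truth tumor mask is recorded before halo convolution; the
#' ex-vivo reference is the mean noise-free, full-contact in-mask signal, so
#' the measured in-vivo/ex-vivo contact score recovers \code{c}.
#'
#' Pixels outside the circular field are \code{NA} (invalid), never zero.
#'
#' @param baseline latent normal-tissue baseline, AFU.
#' @param intervalMin injection-to-imaging interval, minutes.
#' @param config a [GeneratorConfig-class].
#' @param contact contact factor in (0, 1].
#' @param tumor \code{NULL}, or \code{list(cx, cy, rPx, ratio, exposure)}.
#' @param hotspot \code{NULL}, or \code{list(cx, cy, rPx, ratio)}.
#' @param marginId,fieldIndex identifiers stored on the result.
#' @return a [MarginField-class].
#' @export
renderField <- function(baseline, intervalMin, config = generatorConfig(),
                        contact = 1, tumor = NULL, hotspot = NULL,
                        marginId = "margin", fieldIndex = 1L) {
  n <- config@imageSizePx
  fov <- circularFieldMask(n)
  act <- activationFraction(intervalMin, config@activationHalftimeMin)

  truth <- matrix(FALSE, n, n)
  rel <- matrix(1, n, n)
  if (!is.null(tumor)) {
    ind <- discMask(n, tumor$cx, tumor$cy, tumor$rPx) & fov
    truth <- ind
    reff <- 1 + (tumor$ratio - 1) * tumor$exposure
    rel <- 1 + (reff - 1) * haloProfile(ind, config@haloSigmaPx)
  }
  if (!is.null(hotspot)) {
    hind <- discMask(n, hotspot$cx, hotspot$cy, hotspot$rPx) & fov
    rel <- pmax(rel, 1 + (hotspot$ratio - 1) * hind)
  }

  clean <- act * baseline * rel
  exVivoRef <- mean(clean[fov])

  if (config@noiseCv > 0) {
    s <- sqrt(log(1 + config@noiseCv^2))
    noise <- matrix(stats::rlnorm(n * n, meanlog = -s^2 / 2, sdlog = s), n, n)
  } else {
    noise <- 1
  }
  px <- contact * clean * noise
  px[!fov] <- NA_real_

  new("MarginField", marginId = as.character(marginId),
      fieldIndex = as.integer(fieldIndex), pixels = px,
      circularMask = fov, truthMask = truth,
      contactFactor = as.numeric(contact),
      exVivoReference = exVivoRef)
}

#' Generate a synthetic patient cohort with imaged margin surfaces
#'
#' Draws patients (injection timing, latent normal-tissue baseline,
#' patient-level exclusion flags), one margin surface per orientation and
#' stage (intermediate and final), renders every field of view with the
#' pixel model of [renderField()], and attaches a shaved-specimen
#' histopathology finding consistent with the planted ground truth. Each
#' patient also receives tumor-free initialisation-scan fields from which the
#' normal-tissue baseline is later estimated.
#'
#' The configuration seed fully determines the cohort; the caller's RNG
#' state is restored on exit.
#'
#' @param config a [GeneratorConfig-class].
#' @return a [MarginCohort-class].
#' @examples
#' co <- generateCohort(generatorConfig(nPatients = 2, imageSizePx = 48,
#'                                      seed = 7))
#' co
#' @export
generateCohort <- function(config = generatorConfig()) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  old <- .saveRngState()
  on.exit(.restoreRngState(old), add = TRUE)
  set.seed(config@seed)

  np <- config@nPatients
  pid <- sprintf("P%03d", seq_len(np))
  short <- stats::runif(np) < config@shortIntervalRate
  interval <- ifelse(short,
                     stats::runif(np, 30, 100),
                     stats::runif(np, config@intervalRangeMin[1],
                                  config@intervalRangeMin[2]))
  sdl <- sqrt(log(1 + config@baselineCv^2))
  baseline <- stats::rlnorm(np, meanlog = log(config@baselineMean) -
                              sdl^2 / 2, sdlog = sdl)
  patientsDf <- data.frame(
    patient_id = pid,
    injection_to_imaging_min = interval,
    baseline_true = baseline,
    dose_ok = stats::runif(np) >= config@doseFailureRate,
    hematoma = stats::runif(np) < config@hematomaRate,
    data_lost = stats::runif(np) < config@dataLossRate,
    stringsAsFactors = FALSE)

  n <- config@imageSizePx
  rField <- n / 2
  surfaces <- list()
  scans <- vector("list", np)
  names(scans) <- pid

  for (i in seq_len(np)) {
    scans[[i]] <- lapply(seq_len(config@initScanFields), function(k)
      renderField(baseline[i], interval[i], config, contact = 1,
                  marginId = paste0(pid[i], "_init"), fieldIndex = k))
    for (stg in c("intermediate", "final")) {
      for (ori in config@orientations) {
        mid <- paste(pid[i], substr(stg, 1, 3), ori, sep = "_")
        hasTumor <- stats::runif(1) < config@tumorPrevalencePerMargin
        tumor <- NULL
        hp <- histopathFinding("benign", specimenKind = "shave",
                               tumorPresent = FALSE)
        if (hasTumor) {
          rfrac <- stats::runif(1, config@tumorRadiusFracRange[1],
                                config@tumorRadiusFracRange[2])
          rPx <- rfrac * n
          maxOff <- max(0, 0.9 * rField - rPx)
          off <- stats::runif(1, 0, maxOff)
          ang <- stats::runif(1, 0, 2 * pi)
          ratio <- max(1.5, stats::rnorm(1, config@tnRatioMean,
                                         config@tnRatioSd))
          occ <- stats::runif(1) < config@occultTumorRate
          expo <- if (occ)
            stats::runif(1, config@occultAttenuationRange[1],
                         config@occultAttenuationRange[2]) else 1
          tumor <- list(cx = (n + 1) / 2 + off * cos(ang),
                        cy = (n + 1) / 2 + off * sin(ang),
                        rPx = rPx, ratio = ratio, exposure = expo)
          hist <- sample(c("IDC", "ILC", "IC_mixed", "DCIS"), 1,
                         prob = c(0.55, 0.11, 0.07, 0.27))
          if (hist == "DCIS") {
            hp <- histopathFinding("DCIS", specimenKind = "shave",
                                   distanceToInkMm = stats::runif(1, 0, 1.9))
          } else {
            hp <- histopathFinding(hist, specimenKind = "shave",
                                   distanceToInkMm = 0, onInk = TRUE)
          }
        }
        hot <- NULL
        if (stats::runif(1) < config@benignHotspotRate) {
          hr <- stats::runif(1, config@hotspotRatioRange[1],
                             config@hotspotRatioRange[2])
          hrad <- stats::runif(1, config@hotspotRadiusFracRange[1],
                               config@hotspotRadiusFracRange[2]) * n
          hoff <- stats::runif(1, 0, max(0, 0.85 * rField - hrad))
          hang <- stats::runif(1, 0, 2 * pi)
          hot <- list(cx = (n + 1) / 2 + hoff * cos(hang),
                      cy = (n + 1) / 2 + hoff * sin(hang),
                      rPx = hrad, ratio = hr)
        }
        flds <- lapply(seq_len(config@fieldsPerMargin), function(k) {
          fail <- stats::runif(1) < config@contactFailureRate
          ct <- if (fail)
            stats::runif(1, config@contactFailureRange[1],
                         config@contactFailureRange[2])
          else stats::runif(1, config@contactRange[1], config@contactRange[2])
          renderField(baseline[i], interval[i], config, contact = ct,
                      tumor = if (k == 1L) tumor else NULL,
                      hotspot = if (k == 1L) hot else NULL,
                      marginId = mid, fieldIndex = k)
        })
        surfaces[[length(surfaces) + 1L]] <-
          new("MarginSurface", marginId = mid, patientId = pid[i],
              orientation = ori, stage = stg, fields = flds, histopath = hp)
      }
    }
  }

  new("MarginCohort", patients = patientsDf, surfaces = surfaces,
      initScans = scans, config = config)
}

#' Does a margin surface contain tumor (ground truth)?
#'
#' @param surface a [MarginSurface-class].
#' @return \code{TRUE} when any field has a non-empty ground-truth tumor
#'   mask.
#' @export
surfaceContainsTumor <- function(surface) {
  any(vapply(surface@fields, function(f) any(f@truthMask), logical(1)))
}

#' Render one transected-specimen image with labelled regions
#'
#' Emulates the ex-vivo measurement of tumor-to-normal signal ratios on
#' transected lumpectomy specimens: a cross-section image with a known tumor
#' region and a normal region chosen far enough from the tumor that the halo
#' contribution is negligible.
#'
#' @param baseline latent baseline, AFU.
#' @param ratio the drawn T:N ratio for this specimen.
#' @param config a [GeneratorConfig-class].
#' @return list with elements \code{field} (a [MarginField-class]; its
#'   \code{truthMask} is the tumor region) and \code{normalMask} (logical
#'   matrix, halo-free normal region).
#' @export
renderTransectedSpecimen <- function(baseline, ratio,
                                     config = generatorConfig()) {
  n <- config@imageSizePx
  rPx <- mean(config@tumorRadiusFracRange) * n
  ctr <- (n + 1) / 2
  # plateau-phase imaging, full contact: the ratio is a tissue property
  fld <- renderField(baseline, intervalMin = 240, config, contact = 1,
                     tumor = list(cx = ctr, cy = ctr, rPx = rPx,
                                  ratio = ratio, exposure = 1),
                     marginId = "transect")
  # the normal region is exactly where the halo profile vanishes, so the
  # noise-free tumor/normal mean ratio reproduces the drawn ratio exactly
  ind <- discMask(n, ctr, ctr, rPx) & fld@circularMask
  k <- haloProfile(ind, config@haloSigmaPx)
  normal <- fld@circularMask & k == 0
  list(field = fld, normalMask = normal)
}

#' Generate a batch of transected specimens
#'
#' Draws one T:N ratio per specimen around \code{tnRatioMean} and renders
#' each cross-section with [renderTransectedSpecimen()].
#'
#' @param nSpecimens number of specimens.
#' @param config a [GeneratorConfig-class].
#' @param seed integer seed; defaults to the configuration seed.
#' @return list of specimens as returned by [renderTransectedSpecimen()],
#'   with the drawn ratio attached as \code{drawnRatio}.
#' @export
generateTransectedSpecimens <- function(nSpecimens = 50,
                                        config = generatorConfig(),
                                        seed = config@seed) {
  old <- .saveRngState()
  on.exit(.restoreRngState(old), add = TRUE)
  set.seed(seed)
  sdl <- sqrt(log(1 + config@baselineCv^2))
  lapply(seq_len(nSpecimens), function(i) {
    b <- stats::rlnorm(1, log(config@baselineMean) - sdl^2 / 2, sdl)
    r <- max(1.5, stats::rnorm(1, config@tnRatioMean, config@tnRatioSd))
    sp <- renderTransectedSpecimen(b, r, config)
    sp$drawnRatio <- r
    sp
  })
}

.saveRngState <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRngState <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
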