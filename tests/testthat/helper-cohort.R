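# Shared fixtures built in code. Cohorts are cached across test files; all
# reduced-resolution cohorts use 48-px grids with the area guard scaled to
# match (2 px at 48 px ~ 9 px at the default 256 px).

.fixtureCache <- new.env(parent = emptyenv())

cachedCohort <- function(name, config) {
  if (is.null(.fixtureCache[[name]]))
    .fixtureCache[[name]] <- generateCohort(config)
  .fixtureCache[[name]]
}

smallDetection <- function(minAreaPx = 2L) detectionConfig(minAreaPx)

# default-statistics cohort at reduced resolution (40 patients, 480 surfaces)
defaultSmallCohort <- function() {
  cachedCohort("default40",
               generatorConfig(nPatients = 40, imageSizePx = 48, seed = 101))
}

# fully separable conditions: low noise, no hotspots, no occult tumors,
# perfect contact; used for the perfect-separation invariants (a little
# pixel noise keeps normal maxima strictly above 1 without overlapping the
# tumor cluster)
separableConfig <- function(seed = 202) {
  generatorConfig(nPatients = 6, imageSizePx = 48, seed = seed,
                  noiseCv = 0.05, benignHotspotRate = 0, occultTumorRate = 0,
                  contactFailureRate = 0, contactRange = c(1, 1),
                  tumorPrevalencePerMargin = 0.3)
}

separableCohort <- function() cachedCohort("separable", separableConfig())

# a minimal constant-valued field for arithmetic identities
constantField <- function(value, sizePx = 32L, marginId = "const",
                          fieldIndex = 1L) {
  fov <- circularFieldMask(sizePx)
  px <- matrix(value, sizePx, sizePx)
  px[!fov] <- NA_real_
  new("MarginField", marginId = marginId, fieldIndex = as.integer(fieldIndex),
      pixels = px, circularMask = fov,
      truthMask = matrix(FALSE, sizePx, sizePx),
      contactFactor = 1, exVivoReference = value)
}

# independent brute-force confusion-matrix oracle for ROC checks
bruteForceRoc <- function(values, labels) {
  cand <- sort(unique(values))
  out <- data.frame(coefficient = cand, sensitivity = NA_real_,
                    specificity = NA_real_)
  for (i in seq_along(cand)) {
    tp <- fp <- tn <- fn <- 0
    for (j in seq_along(values)) {
      pred <- values[j] > cand[i]
      if (pred && labels[j]) tp <- tp + 1
      if (pred && !labels[j]) fp <- fp + 1
      if (!pred && !labels[j]) tn <- tn + 1
      if (!pred && labels[j]) fn <- fn + 1
    }
    out$sensitivity[i] <- tp / (tp + fn)
    out$specificity[i] <- tn / (tn + fp)
  }
  out
}
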