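# Baseline estimation, normalization, ROC construction, coefficient
# selection and the pooled threshold model.

test_that("baseline estimation is the pooled in-mask pixel median", {
  expect_equal(estimateBaseline(constantField(7))$baselineHat, 7)
  est <- estimateBaseline(list(constantField(4), constantField(8)))
  expect_equal(est$baselineHat, 6)
  expect_equal(est$nPixelsUsed,
               2 * sum(circularMask(constantField(4))))
  expect_error(estimateBaseline(list()), "at least one")
})

test_that("baseline recovery from noisy initialisation scans is unbiased", {
  cfg <- generatorConfig(noiseCv = 0.1, imageSizePx = 48, seed = 9)
  set.seed(9)
  act <- activationFraction(240, cfg@activationHalftimeMin)
  flds <- lapply(1:3, function(k) renderField(100, 240, cfg))
  est <- estimateBaseline(flds)
  expect_equal(est$baselineHat, act * 100, tolerance = 0.02)
})

test_that("normalization divides by the baseline", {
  expect_equal(normalizeSignal(100, 100), 1.0)
  expect_equal(normalizeSignal(390, 100), 3.9)
  expect_equal(normalizeSignal(0, 100), 0)
  b <- estimateBaseline(constantField(50))
  expect_equal(normalizeSignal(75, b), 1.5)
  expect_error(normalizeSignal(1, 0), "positive")
})

test_that("ROC points match the brute-force confusion-matrix oracle", {
  expect_equal(buildRoc(c(1, 2), c(FALSE, TRUE)),
               data.frame(coefficient = c(1, 2), sensitivity = c(1, 0),
                          specificity = c(1, 1)))
  set.seed(42)
  values <- c(rlnorm(120, 0, 0.5), rlnorm(80, 1, 0.5))
  labels <- c(rep(FALSE, 120), rep(TRUE, 80))
  roc <- buildRoc(values, labels)
  oracle <- bruteForceRoc(values, labels)
  expect_equal(roc, oracle)
  # monotonicity along the coefficient axis
  expect_true(all(diff(roc$sensitivity) <= 0))
  expect_true(all(diff(roc$specificity) >= 0))
  expect_error(buildRoc(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("coefficient selection maximizes Youden's J, ties to the left", {
  roc <- data.frame(coefficient = c(0.5, 2.0, 4.0),
                    sensitivity = c(1.0, 0.9, 0.3),
                    specificity = c(0.2, 0.9, 1.0))
  expect_equal(selectCoefficient(roc), 2.0)
  tie <- data.frame(coefficient = c(1, 2, 3),
                    sensitivity = c(1, 1, 0.5),
                    specificity = c(0.8, 0.8, 1.0))
  expect_equal(selectCoefficient(tie), 1)

  set.seed(7)
  values <- c(rlnorm(300, 0, 0.6), rlnorm(200, 0.9, 0.6))
  labels <- c(rep(FALSE, 300), rep(TRUE, 200))
  roc <- buildRoc(values, labels)
  j <- roc$sensitivity + roc$specificity - 1
  oracle <- roc$coefficient[which.max(j)]
  expect_equal(selectCoefficient(roc), oracle)
})

test_that("per-patient thresholds are coefficient times baseline", {
  co <- separableCohort()
  m <- fitThresholdModel(co, smallDetection())
  expect_equal(thresholds(m), coefficient(m) * baselines(m))
  # proportionality: baselines in ratio r give thresholds in ratio r
  b <- baselines(m)
  expect_equal(thresholds(m)[[1]] / thresholds(m)[[2]], b[[1]] / b[[2]])
  # on separable data the coefficient sits strictly between 1 and the T:N mean
  expect_gt(coefficient(m), 1)
  expect_lt(coefficient(m), 3.9)
  # missing baseline is a calibration error
  broken <- co
  broken@initScans <- broken@initScans[-1]
  expect_error(fitThresholdModel(broken, smallDetection()),
               "initialisation scans")
})

test_that("low-noise separable calibration achieves perfect separation", {
  co <- separableCohort()
  m <- fitThresholdModel(co, smallDetection())
  roc <- rocPoints(m)
  at <- roc[roc$coefficient == coefficient(m), ]
  expect_equal(at$sensitivity, 1)
  expect_equal(at$specificity, 1)
})

test_that("normalization is scale-equivariant end to end", {
  cfg <- generatorConfig(noiseCv = 0.05, imageSizePx = 48, seed = 13)
  set.seed(13)
  tum <- list(cx = 24, cy = 24, rPx = 7, ratio = 3.9, exposure = 1)
  f <- renderField(100, 240, cfg, tumor = tum)
  surf <- new("MarginSurface", marginId = "m", patientId = "p",
              orientation = "superior", stage = "final",
              fields = list(f), histopath = histopathFinding("IDC",
                onInk = TRUE))
  k <- 3.7
  f2 <- f
  f2@pixels <- f@pixels * k
  f2@exVivoReference <- f@exVivoReference * k
  surf2 <- surf; surf2@fields <- list(f2)

  b <- 100; det <- smallDetection()
  expect_equal(surfaceSignal(surf, b, det), surfaceSignal(surf2, k * b, det))
  coefThr <- 2.0
  r1 <- classifyImage(f, coefThr * b, det)
  r2 <- classifyImage(f2, coefThr * k * b, det)
  expect_identical(r1@positive, r2@positive)
  expect_identical(r1@highlightMask, r2@highlightMask)
})
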