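# Synthetic cohort generator: determinism, ground truth, signal model.

test_that("cohort generation is seed-deterministic and validates its config", {
  cfg <- generatorConfig(nPatients = 5, imageSizePx = 48, seed = 1)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(c1, c2)
  c3 <- generateCohort(generatorConfig(nPatients = 5, imageSizePx = 48,
                                       seed = 2))
  expect_false(identical(patients(c1)$baseline_true,
                         patients(c3)$baseline_true))

  expect_error(generatorConfig(tnRatioMean = 0.9), "tnRatioMean")
  expect_error(generatorConfig(tumorPrevalencePerMargin = 1.5),
               "tumorPrevalencePerMargin")
  expect_error(generatorConfig(imageSizePx = 16), "imageSizePx")
})

test_that("zero tumor prevalence yields tumor-free surfaces everywhere", {
  co <- generateCohort(generatorConfig(nPatients = 2, imageSizePx = 48,
                                       tumorPrevalencePerMargin = 0,
                                       seed = 3))
  expect_false(any(vapply(surfaces(co), surfaceContainsTumor, logical(1))))
})

test_that("tumor-surface fraction is binomially consistent with prevalence", {
  co <- defaultSmallCohort()
  nSurf <- length(surfaces(co))
  k <- sum(vapply(surfaces(co), surfaceContainsTumor, logical(1)))
  p <- generatorCfg(co)@tumorPrevalencePerMargin
  # exact binomial 99% bounds computed from qbinom
  expect_gte(k, qbinom(0.005, nSurf, p))
  expect_lte(k, qbinom(0.995, nSurf, p))
})

test_that("noise-free renders reproduce the pixel model exactly", {
  cfg <- generatorConfig(noiseCv = 0, imageSizePx = 48, seed = 1)
  act <- activationFraction(240, cfg@activationHalftimeMin)

  # identity case: normal tissue at full contact equals A(t) * B exactly
  f <- renderField(100, 240, cfg, contact = 1)
  expect_equal(unique(pixels(f)[circularMask(f)]), act * 100)
  # at long intervals the activation plateau makes pixels ~ B itself
  fLate <- renderField(100, 5000, cfg, contact = 1)
  expect_equal(mean(pixels(fLate)[circularMask(fLate)]), 100,
               tolerance = 0.002)
  # contact attenuation scales every pixel
  fHalf <- renderField(100, 240, cfg, contact = 0.5)
  expect_equal(pixels(fHalf)[circularMask(fHalf)],
               0.5 * pixels(f)[circularMask(f)])

  # tumor construction: in-tumor / far-field ratio equals the drawn R
  tum <- list(cx = 24.5, cy = 24.5, rPx = 8, ratio = 3.9, exposure = 1)
  ft <- renderField(100, 240, cfg, tumor = tum)
  expect_equal(max(pixels(ft)[truthMask(ft)]) /
                 min(pixels(ft)[circularMask(ft)]), 3.9)
  # halo: pixels strictly outside the truth mask exceed 1.5x baseline
  outside <- circularMask(ft) & !truthMask(ft)
  expect_true(any(pixels(ft)[outside] > 1.5 * act * 100))
  # truth mask recorded before halo convolution: the halo is not truth
  expect_lt(sum(truthMask(ft)), sum(pixels(ft) > 1.2 * act * 100,
                                    na.rm = TRUE))
})

test_that("activation and contact are monotone in the pixel model", {
  expect_true(all(diff(activationFraction(c(10, 50, 101, 402, 1000))) > 0))
  cfg <- generatorConfig(noiseCv = 0, imageSizePx = 48)
  f1 <- renderField(100, 240, cfg, contact = 0.7)
  f2 <- renderField(100, 240, cfg, contact = 0.9)
  expect_true(all(pixels(f2)[circularMask(f2)] >=
                    pixels(f1)[circularMask(f1)]))
})

test_that("noise-free transected specimens recover the drawn T:N ratio", {
  cfg <- generatorConfig(noiseCv = 0, imageSizePx = 64, seed = 5)
  sp <- renderTransectedSpecimen(100, 4.0, cfg)
  est <- estimateTnRatio(list(sp))
  expect_equal(est$ratioHat, 4.0, tolerance = 1e-12)
})
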