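# Cohort-level performance summaries, T:N estimation and the end-to-end
# evaluation properties.

test_that("performance summary matches a hand-counted confusion matrix", {
  set.seed(31)
  calls <- sample(c("TP", "FP", "TN", "FN"), 100, replace = TRUE,
                  prob = c(0.2, 0.2, 0.5, 0.1))
  stage <- sample(c("intermediate", "final"), 100, replace = TRUE)
  perf <- performanceSummary(data.frame(call = calls, stage = stage))
  tp <- sum(calls == "TP"); fn <- sum(calls == "FN")
  tn <- sum(calls == "TN"); fp <- sum(calls == "FP")
  expect_equal(perf$sensitivity, tp / (tp + fn))
  expect_equal(perf$specificity, tn / (tn + fp))
  expect_equal(sum(perf$counts), 100)            # counts are conserved
  expect_equal(sum(perf$perStage$n), 100)
  # undefined rates surface as NA, never as 0 or 1
  allTp <- performanceSummary(data.frame(call = rep("TP", 5)))
  expect_equal(allTp$sensitivity, 1)
  expect_true(is.na(allTp$specificity))
  expect_error(performanceSummary(data.frame(call = "XX")), "unknown")
})

test_that("the positive-final-margin table yields 100% sensitivity", {
  t3 <- finalMarginTable()
  calls <- vapply(seq_len(nrow(t3)), function(i)
    adjudicateReading(t3$device_reading[i],
                      shave = histopathFinding(t3$additional_histology[i],
                        tumorPresent = t3$additional_histology[i] != "benign"),
                      specimenSurface = rowFinding(t3[i, ],
                        "main_specimen_surface")), character(1))
  perf <- performanceSummary(data.frame(call = calls))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$counts[["TP"]], 4)
})

test_that("T:N estimation is exact in the noise-free identity cases", {
  cfg <- generatorConfig(noiseCv = 0, imageSizePx = 64)
  sp <- renderTransectedSpecimen(80, 4.0, cfg)
  expect_equal(estimateTnRatio(list(sp))$ratioHat, 4.0, tolerance = 1e-12)
  # identical tumor and normal regions give exactly 1
  sp$normalMask <- truthMask(sp$field)
  expect_equal(estimateTnRatio(list(sp))$ratioHat, 1.0)
  expect_error(estimateTnRatio(list()), "no specimens")
})

test_that("mean T:N over noisy specimens stays in the reported band", {
  sps <- generateTransectedSpecimens(50, generatorConfig(imageSizePx = 64),
                                     seed = 1)
  est <- estimateTnRatio(sps)
  expect_equal(est$nSpecimens, 50)
  expect_gte(est$ratioHat, 3.78)
  expect_lte(est$ratioHat, 4.11)
  # per-specimen estimates track the drawn ratios closely
  drawn <- vapply(sps, function(s) s$drawnRatio, numeric(1))
  expect_equal(est$perSpecimen, drawn, tolerance = 0.05)
})

test_that("separable-cohort evaluation is perfect and confusion is conserved", {
  co <- separableCohort()
  res <- evaluateCohort(co, detection = smallDetection())
  expect_equal(res$report$sensitivity, 1)
  expect_equal(res$report$specificity, 1)
  expect_equal(sum(unlist(res$report$confusion)),
               res$report$n_surfaces_total)
  expect_gt(res$report$coefficient, 1)
  expect_lt(res$report$coefficient, 3.9)
})

test_that("disabling QC on a poor-contact cohort lowers sensitivity", {
  cfg <- generatorConfig(nPatients = 12, imageSizePx = 48, seed = 33,
                         tumorPrevalencePerMargin = 0.3,
                         contactFailureRate = 0.4,
                         benignHotspotRate = 0, occultTumorRate = 0)
  co <- cachedCohort("poorContact", cfg)
  det <- smallDetection()
  withQc <- evaluateCohort(co, detection = det, coefficient = 2)
  noQc <- evaluateCohort(co, detection = det, coefficient = 2,
                         applyQc = FALSE)
  expect_gt(withQc$report$sensitivity, noQc$report$sensitivity)
})

test_that("held-out evaluation under default conditions matches the
           reported operating point within ten points", {
  cfg <- generatorConfig(nPatients = 150, imageSizePx = 48, seed = 1)
  co <- cachedCohort("surrogate150", cfg)
  res <- evaluateCohort(co, detection = smallDetection(),
                        evalMode = "leave_one_patient_out")
  expect_gt(res$report$n_tumor_surfaces, 20)
  expect_lt(abs(100 * res$report$sensitivity - 84), 10)
  expect_lt(abs(100 * res$report$specificity - 73), 10)
})
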