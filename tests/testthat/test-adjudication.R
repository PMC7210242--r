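# Margin-status rules, shave arbitration and the clinical-outcome logic.

test_that("margin status applies the on-ink and 2-mm rules", {
  expect_equal(marginStatus(histopathFinding("IDC", onInk = TRUE,
                                             distanceToInkMm = 0)),
               "positive")
  expect_equal(marginStatus(histopathFinding("DCIS", distanceToInkMm = 1.5)),
               "positive")
  # strict '<': exactly 2.0 mm is negative
  expect_equal(marginStatus(histopathFinding("DCIS", distanceToInkMm = 2.0)),
               "negative")
  # invasive rule ignores the 2-mm band
  expect_equal(marginStatus(histopathFinding("ILC", distanceToInkMm = 1,
                                             onInk = FALSE)),
               "negative")
  expect_equal(marginStatus(histopathFinding("benign")), "negative")
  # mixed invasive + DCIS: positive if either component rule fires
  expect_equal(marginStatus(histopathFinding("IDC_DCIS", onInk = TRUE,
                                             distanceToInkMm = 0)),
               "positive")
  expect_equal(marginStatus(histopathFinding("IDC_DCIS", onInk = FALSE,
                                             distanceToInkMm = 1.2)),
               "positive")
  expect_equal(marginStatus(histopathFinding("IDC_DCIS", onInk = FALSE,
                                             distanceToInkMm = 3)),
               "negative")
  expect_error(marginStatus(histopathFinding("DCIS")), "distance")
})

test_that("adjudication arbitrates in favour of the shave when present", {
  benignSurface <- histopathFinding("benign",
                                    specimenKind = "main_specimen_surface")
  # tumor anywhere in the shave is a TP even when far from ink
  shaveFar <- histopathFinding("IDC", distanceToInkMm = 3, onInk = FALSE)
  expect_equal(adjudicateReading("positive", shaveFar, benignSurface), "TP")
  expect_equal(adjudicateReading("negative", shaveFar, benignSurface), "FN")
  # a benign shave overrides a positive-looking specimen surface
  posSurface <- histopathFinding("IDC", onInk = TRUE,
                                 specimenKind = "main_specimen_surface")
  benignShave <- histopathFinding("benign")
  expect_equal(adjudicateReading("positive", benignShave, posSurface), "FP")
  # without a shave, the specimen-surface margin status decides
  expect_equal(adjudicateReading("positive", NULL, posSurface), "TP")
  expect_equal(adjudicateReading("negative", NULL, benignSurface), "TN")
  dcisFar <- histopathFinding("DCIS", distanceToInkMm = 4,
                              specimenKind = "main_specimen_surface")
  expect_equal(adjudicateReading("positive", NULL, dcisFar), "FP")
})

test_that("clinical outcomes follow the surgeon-action logic", {
  expect_equal(clinicalOutcome("positive", TRUE, TRUE), "spared_reoperation")
  expect_equal(clinicalOutcome("positive", FALSE, TRUE),
               "reoperation_required")
  expect_equal(clinicalOutcome("negative", FALSE, FALSE),
               "correctly_predicted_clear")
  expect_equal(clinicalOutcome("negative", FALSE, NA), "no_action_needed")
  expect_error(clinicalOutcome("negative", TRUE, TRUE), "inconsistent")
})

test_that("every final-margin row maps to exactly one outcome, summing to 8", {
  t3 <- clinicalOutcomes(finalMarginTable())
  expect_equal(nrow(t3), 8)
  counts <- table(t3$outcome)
  expect_equal(sum(counts), 8)
  expect_equal(unname(counts[["spared_reoperation"]]), 2)
  expect_equal(unname(counts[["reoperation_required"]]), 4)
  expect_equal(unname(counts[["correctly_predicted_clear"]]), 2)
})
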