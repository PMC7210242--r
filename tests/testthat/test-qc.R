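# Eligibility and quality control: timepoint window, contact score,
# exclusion accounting and filter properties.

test_that("injection-to-imaging eligibility respects the 101-min bound", {
  expect_identical(timepointEligible(c(56, 92, 101, 402)),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_error(timepointEligible(0), "positive")
  expect_error(timepointEligible(-5), "positive")
  # configurable bound
  expect_true(timepointEligible(95, qcConfig(minIntervalMin = 90)))
})

test_that("contact score is the in-vivo/ex-vivo ratio with input checks", {
  expect_equal(contactScore(10, 10), 1.0)
  expect_equal(contactScore(8.4, 10), 0.84)
  expect_equal(contactScore(12, 10), 1.2)
  expect_error(contactScore(5, 0), "positive")
  # the 0.84 score sits exactly on the exclusion boundary (<= is excluded)
  qc <- qcConfig()
  expect_true(fluorMargin:::.isPoorContact(contactScore(8.4, 10), qc))
  expect_false(fluorMargin:::.isPoorContact(contactScore(8.5, 10), qc))
})

test_that("enrollment accounting: 45 patients minus 5 exclusions leaves 40", {
  res <- applyExclusions(enrollmentScenario())
  expect_equal(nrow(res$eligible), 40)
  expect_equal(nrow(res$exclusions), 5)
  expect_equal(sort(res$exclusions$reason),
               sort(c("short_interval", "short_interval", "dose_failure",
                      "hematoma_necrosis", "data_lost")))
  expect_true(all(res$exclusions$level == "patient"))
})

test_that("image-level exclusions recover exactly the planted poor contacts", {
  co <- defaultSmallCohort()
  planted <- character()
  for (s in surfaces(co)) for (f in fields(s))
    if (contactFactor(f) <= 0.84)
      planted <- c(planted, paste0(marginId(f), "/", f@fieldIndex))
  res <- applyExclusions(co)
  img <- res$exclusions[res$exclusions$level == "image", ]
  expect_gt(length(planted), 0)
  expect_setequal(img$entity_id, planted)
  expect_true(all(img$reason == "poor_contact"))
  # no eligible field retains a score at or below the cutoff
  scores <- unlist(lapply(surfaces(res$eligible), function(s)
    vapply(fields(s), fieldContactScore, numeric(1))))
  expect_true(all(scores > 0.84))
})

test_that("exclusion filtering is idempotent and monotone in the cutoff", {
  co <- defaultSmallCohort()
  once <- applyExclusions(co)
  twice <- applyExclusions(once$eligible)
  expect_identical(once$eligible, twice$eligible)
  expect_equal(nrow(twice$exclusions), 0)

  excludedAt <- function(cut) {
    res <- applyExclusions(co, qcConfig(contactCutoff = cut))
    res$exclusions$entity_id[res$exclusions$level == "image"]
  }
  low <- excludedAt(0.5); mid <- excludedAt(0.84); high <- excludedAt(0.95)
  expect_true(all(low %in% mid))
  expect_true(all(mid %in% high))
})

test_that("no-failure cohorts pass quality control untouched", {
  co <- separableCohort()
  res <- applyExclusions(co)
  expect_equal(nrow(res$exclusions), 0)
  expect_identical(res$eligible, co)
})
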