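# Image classification, margin aggregation, overlays, and the raster
# primitives backing them.

test_that("median smoothing matches the direct median-of-nine oracle", {
  set.seed(4)
  m <- matrix(runif(144, 0, 500), 12, 12)
  sm <- medianSmooth(m)
  for (rc in list(c(2, 2), c(5, 9), c(11, 3))) {
    r <- rc[1]; cc <- rc[2]
    expect_equal(sm[r, cc], median(m[(r - 1):(r + 1), (cc - 1):(cc + 1)]))
  }
  # an isolated speckle is removed
  m2 <- matrix(1, 7, 7); m2[4, 4] <- 1000
  expect_equal(medianSmooth(m2)[4, 4], 1)
  # masked (invalid) pixels come back NA and never acquire signal
  mask <- matrix(TRUE, 7, 7); mask[1, ] <- FALSE
  expect_true(all(is.na(medianSmooth(m2, mask)[1, ])))
})

test_that("connected components use 8-connectivity deterministically", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal chain
  m[6, 6] <- TRUE
  lab <- labelComponents(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[3, 3])
  expect_identical(labelComponents(m), labelComponents(m))
  expect_equal(max(labelComponents(matrix(FALSE, 3, 3))), 0)
})

test_that("image classification applies strict threshold and area rules", {
  f <- constantField(10)
  expect_error(classifyImage(f, 0), "positive")
  # everything below threshold: negative, empty highlight
  r <- classifyImage(f, 20)
  expect_false(r@positive)
  expect_equal(sum(r@highlightMask), 0)
  # exactly at threshold: strict inequality keeps it negative
  r <- classifyImage(f, 10)
  expect_false(r@positive)
  expect_equal(sum(r@highlightMask), 0)
  # just below threshold: positive with the full field highlighted
  r <- classifyImage(f, 9.99)
  expect_true(r@positive)
  expect_equal(sum(r@highlightMask), sum(circularMask(f)))
})

test_that("a rendered tumor field is detected and overlaps the truth", {
  cfg <- generatorConfig(noiseCv = 0.05, imageSizePx = 48, seed = 21)
  set.seed(21)
  tum <- list(cx = 24, cy = 24, rPx = 7, ratio = 3.9, exposure = 1)
  f <- renderField(100, 240, cfg, contact = 1, tumor = tum)
  act <- activationFraction(240, cfg@activationHalftimeMin)
  r <- classifyImage(f, 2.0 * act * 100, smallDetection())
  expect_true(r@positive)
  expect_gt(sum(r@highlightMask & truthMask(f)), 0)
  expect_gte(r@suprathresholdAreaPx, 2)
})

test_that("raising the threshold shrinks the highlight monotonically", {
  cfg <- generatorConfig(noiseCv = 0.1, imageSizePx = 48, seed = 22)
  set.seed(22)
  tum <- list(cx = 24, cy = 24, rPx = 8, ratio = 3.9, exposure = 1)
  f <- renderField(100, 240, cfg, tumor = tum)
  thr <- seq(50, 400, by = 50)
  prev <- NULL
  prevPos <- TRUE
  for (t in thr) {
    r <- classifyImage(f, t, smallDetection())
    if (!is.null(prev)) {
      expect_true(all(prev | !r@highlightMask))   # mask never grows
      expect_false(!prevPos && r@positive)        # negative never flips back
    }
    prev <- r@highlightMask
    prevPos <- r@positive
  }
})

test_that("margin aggregation is any-field-positive", {
  f <- constantField(10)
  neg <- classifyImage(f, 20)
  pos <- classifyImage(f, 5)
  expect_equal(aggregateMargin(list(neg, neg)), "negative")
  expect_equal(aggregateMargin(list(neg, pos, neg)), "positive")
  expect_equal(aggregateMargin(list(pos)), "positive")
  expect_equal(aggregateMargin(list(neg)), "negative")
  # adding a field can only keep or raise the reading
  expect_equal(aggregateMargin(list(neg, neg, pos)), "positive")
  other <- classifyImage(constantField(10, marginId = "other"), 20)
  expect_error(aggregateMargin(list(neg, other)), "different margins")
  expect_error(aggregateMargin(list()), "at least one")
})

test_that("overlay paints exactly the retained suprathreshold pixels red", {
  f <- constantField(10)
  neg <- classifyImage(f, 20)
  rgb <- renderOverlay(f, neg)
  expect_true(all(rgb[, , 1] == rgb[, , 2] & rgb[, , 2] == rgb[, , 3]))

  cfg <- generatorConfig(noiseCv = 0.05, imageSizePx = 48, seed = 23)
  set.seed(23)
  tum <- list(cx = 24, cy = 24, rPx = 7, ratio = 3.9, exposure = 1)
  ft <- renderField(100, 240, cfg, tumor = tum)
  act <- activationFraction(240, cfg@activationHalftimeMin)
  r <- classifyImage(ft, 2 * act * 100, smallDetection())
  rgb <- renderOverlay(ft, r)
  red <- rgb[, , 1] == 1 & rgb[, , 2] == 0 & rgb[, , 3] == 0
  expect_equal(sum(red), r@suprathresholdAreaPx)
  expect_identical(red, r@highlightMask)

  expect_error(renderOverlay(constantField(10, sizePx = 16), r),
               "does not belong")
})
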