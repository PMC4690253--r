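# small geometry used throughout: ~350 myocardial pixels per slice
smallSpec <- function(...) {
  phantomSpec(imageSize = 48, endoRadius = 14, wallThickness = 8,
              pixelSpacing = 2, ...)
}

test_that("noiseless uniform phantom obeys the mono-exponential decay law", {
  spec <- smallSpec(snr = Inf, segmentSD = 0, textureSD = 0,
                    levelOffsets = c(basal = 0, mid = 0, apical = 0),
                    baselineT2 = 58.7, seed = 1)
  sub <- generatePhantomSubject(spec)
  mags <- seriesMagnitudes(sub$series)
  myo <- seriesMask(sub$series)
  ratio <- mags[, , , 9][myo] / mags[, , , 1][myo]
  expect_equal(unname(range(ratio)), rep(exp(-(76.6 - 15) / 58.7), 2),
               tolerance = 1e-10)
})

test_that("wedge lesion covers the expected fraction of the annulus", {
  spec <- smallSpec(seed = 3, lesions = list(
    lesionSpec(slices = 1:2, centerDeg = 120, extentDeg = 60,
               transmuralFraction = 1, deltaT2 = 15)))
  sub <- generatePhantomSubject(spec)
  lm1 <- sub$truth@lesionMask[, , 1]
  annulus <- sub$truth@segmentLabels[, , 1] > 0
  expect_equal(sum(lm1) / sum(annulus), 60 / 360, tolerance = 0.12)
  # untouched slice
  expect_equal(sum(sub$truth@lesionMask[, , 3]), 0)
})

test_that("identical seeds reproduce the subject bit for bit", {
  a <- generatePhantomSubject(smallSpec(seed = 7))
  b <- generatePhantomSubject(smallSpec(seed = 7))
  expect_identical(seriesMagnitudes(a$series), seriesMagnitudes(b$series))
  expect_identical(a$truth@trueT2, b$truth@trueT2)
})

test_that("segment labels partition the myocardium on every slice", {
  sub <- generatePhantomSubject(smallSpec(seed = 9))
  labels <- sub$truth@segmentLabels
  myo <- seriesMask(sub$series)
  for (k in 1:6) {
    lab <- labels[, , k]
    expect_identical(lab > 0, myo[, , k])
    nseg <- if (k <= 4) 6L else 4L
    expect_equal(length(unique(lab[lab > 0])), nseg)
  }
  expect_identical(sum(labels > 0), sum(myo))
})

test_that("raising a lesion's deltaT2 raises only the affected segments", {
  mk <- function(d) generatePhantomSubject(smallSpec(
    seed = 13, lesions = list(lesionSpec(slices = 3:4, centerDeg = 95,
                                         extentDeg = 80, deltaT2 = d))))
  subs <- lapply(c(0, 10, 20), mk)
  labels <- subs[[1]]$truth@segmentLabels
  segMean <- function(sub) vapply(1:16, function(s)
    mean(sub$truth@trueT2[labels == s]), numeric(1))
  m <- vapply(subs, segMean, numeric(16))
  affected <- unique(labels[subs[[3]]$truth@lesionMask])
  expect_true(length(affected) >= 1)
  for (s in affected) {
    expect_lt(m[s, 1], m[s, 2])
    expect_lt(m[s, 2], m[s, 3])
  }
  for (s in setdiff(1:16, affected))
    expect_equal(m[s, 1], m[s, 3], tolerance = 1e-12)
})

test_that("a lesion clipped entirely away warns", {
  spec <- smallSpec(seed = 2, lesions = list(
    lesionSpec(slices = 40L, centerDeg = 0, extentDeg = 60, deltaT2 = 15)))
  expect_warning(generatePhantomSubject(spec), "no myocardial pixels")
})

test_that("invalid phantom and lesion parameters are rejected", {
  expect_error(phantomSpec(endoRadius = -1), "endoRadius")
  expect_error(phantomSpec(nSlices = 2), "nSlices")
  expect_error(phantomSpec(snr = 0), "snr")
  expect_error(phantomSpec(echoTimes = c(30, 15, 20)), "increasing")
  expect_error(lesionSpec(1, 0, extentDeg = 400), "extentDeg")
  expect_error(lesionSpec(1, 0, 60, transmuralFraction = 0), "transmural")
})
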