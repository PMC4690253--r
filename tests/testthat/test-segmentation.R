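ring <- function(r, n = 120) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(th), r * sin(th))
}
oneSlice <- function(level = "basal", rv = 60)
  contourSet(list(list(endo = ring(14), epi = ring(22), rvAngle = rv,
                       level = level)))

test_that("basal sectors partition the annulus into six segments", {
  lab <- buildSegmentMasks(oneSlice(), imageSize = 48, pixelSpacing = 2)
  inside <- lab[, , 1] > 0
  expect_setequal(unique(lab[, , 1][inside]), 1:6)
  # every annulus pixel carries exactly one label by construction; check the
  # sector sizes are balanced to within discretisation
  counts <- table(lab[, , 1][inside])
  expect_lt(diff(range(counts)) / mean(counts), 0.25)
})

test_that("rotating the RV insertion by +60 degrees permutes basal labels cyclically", {
  l0 <- buildSegmentMasks(oneSlice(rv = 60), 48, 2)[, , 1]
  l1 <- buildSegmentMasks(oneSlice(rv = 120), 48, 2)[, , 1]
  # sector boundaries advance one position: 1 -> 6 -> 5 -> ... -> 2 -> 1
  inside <- l0 > 0
  remap <- l1[inside] == ifelse(l0[inside] == 1L, 6L, l0[inside] - 1L)
  expect_gt(mean(remap), 0.98)
})

test_that("apical slices get exactly the four apical segments", {
  lab <- buildSegmentMasks(oneSlice(level = "apical"), 48, 2)
  inside <- lab > 0
  expect_setequal(unique(lab[inside]), 13:16)
})

test_that("mid-level labels are offset into 7..12", {
  lab <- buildSegmentMasks(oneSlice(level = "mid"), 48, 2)
  expect_setequal(unique(lab[lab > 0]), 7:12)
})

test_that("an endocardium outside the epicardium is rejected", {
  expect_error(contourSet(list(list(endo = ring(25), epi = ring(22),
                                    rvAngle = 0, level = "basal"))),
               "inside")
})

test_that("segment statistics reproduce hand-computed mean and sample SD", {
  t2 <- array(NA_real_, c(4, 4, 1))
  lab <- array(0L, c(4, 4, 1))
  t2[1:4] <- c(50, 50, 70, 70)
  lab[1:4] <- 1L
  tab <- segmentStatistics(t2, lab, minPixels = 2)
  expect_equal(tab$mean_T2_ms[1], 60)
  expect_equal(tab$pixel_SD_ms[1], sqrt(400 / 3), tolerance = 1e-12)
  expect_equal(tab$n_pixels[1], 4L)
  # a constant segment has zero pixel-SD
  t2[1:4] <- 60
  tab2 <- segmentStatistics(t2, lab, minPixels = 2)
  expect_equal(tab2$pixel_SD_ms[1], 0)
  expect_equal(tab2$mean_T2_ms[1], 60)
})

test_that("pixel counts are conserved between map and segment table", {
  sub <- generatePhantomSubject(phantomSpec(imageSize = 48, endoRadius = 14,
                                            wallThickness = 8, seed = 6))
  map <- fitMap(sub$series, "loglinear")
  tab <- segmentStatistics(map, sub$truth@segmentLabels)
  expect_equal(sum(tab$n_pixels),
               sum(fitConverged(map) & sub$truth@segmentLabels > 0))
  expect_equal(nrow(tab), 16L)
  expect_identical(tab$level, segmentLevel(1:16))
})

test_that("uniform lesion-free phantom yields 16 agreeing segmental means", {
  spec <- phantomSpec(imageSize = 64, endoRadius = 18, wallThickness = 9,
                      snr = Inf, segmentSD = 0, textureSD = 0,
                      levelOffsets = c(basal = 0, mid = 0, apical = 0),
                      seed = 4)
  sub <- generatePhantomSubject(spec)
  tab <- segmentStatistics(fitMap(sub$series, "loglinear"),
                           sub$truth@segmentLabels)
  expect_lt(diff(range(tab$mean_T2_ms)), 1)
})

test_that("a wedge lesion inside one segment raises only that segment", {
  # segment 1 spans 60..120 degrees with the default RV angle
  mk <- function(lesions = list())
    generatePhantomSubject(phantomSpec(
      imageSize = 64, endoRadius = 18, wallThickness = 9, seed = 8,
      segmentSD = 0, textureScatter = 0,
      lesions = lesions))
  les <- lesionSpec(slices = 1:2, centerDeg = 90, extentDeg = 40,
                    transmuralFraction = 1, deltaT2 = 18)
  s0 <- mk(); s1 <- mk(list(les))
  t0 <- segmentStatistics(fitMap(s0$series, "loglinear"),
                          s0$truth@segmentLabels)
  t1 <- segmentStatistics(fitMap(s1$series, "loglinear"),
                          s1$truth@segmentLabels)
  d <- t1$mean_T2_ms - t0$mean_T2_ms
  expect_equal(which.max(d), 1L)
  expect_gt(d[1], 8)
  expect_lt(max(abs(d[-1])), 3)
})

test_that("a lesion straddling two segments raises pixel-SD in both", {
  mk <- function(lesions = list())
    generatePhantomSubject(phantomSpec(
      imageSize = 64, endoRadius = 18, wallThickness = 9, seed = 12,
      segmentSD = 0, textureScatter = 0, lesions = lesions))
  # boundary between segments 1 and 2 sits at 120 degrees
  les <- lesionSpec(slices = 1:2, centerDeg = 120, extentDeg = 60,
                    transmuralFraction = 1, deltaT2 = 18, textureFactor = 1)
  s0 <- mk(); s1 <- mk(list(les))
  t0 <- segmentStatistics(fitMap(s0$series, "loglinear"),
                          s0$truth@segmentLabels)
  t1 <- segmentStatistics(fitMap(s1$series, "loglinear"),
                          s1$truth@segmentLabels)
  expect_gt(t1$pixel_SD_ms[1], t0$pixel_SD_ms[1] + 1)
  expect_gt(t1$pixel_SD_ms[2], t0$pixel_SD_ms[2] + 1)
})
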