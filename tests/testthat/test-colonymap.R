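test_that("the sliding-window grid has the analytic number of positions", {
  ## full-frame geometry: floor((2751-30)/10)+1 by floor((2206-30)/10)+1
  g <- windowGrid(2751, 2206, 30, 10)
  expect_equal(length(g$rows), 273)
  expect_equal(length(g$cols), 218)
  expect_equal(length(g$rows) * length(g$cols), 59514)
  ## frame exactly one window
  g1 <- windowGrid(30, 30, 30, 10)
  expect_equal(c(length(g1$rows), length(g1$cols)), c(1, 1))
  expect_error(windowGrid(100, 100, 30, 0), "step")
  expect_error(windowGrid(20, 100, 30, 10), "smaller")
})

test_that("non-overlapping segmentation equals independent per-window classification", {
  m <- fixtureTrainedModel()
  sc <- generateColonyImage(fixtureSceneSpec(17))
  img <- sc$image[1:90, 1:90, , drop = FALSE]
  sm <- segmentFrame(img, m, window = 30, step = 30)
  expect_equal(dim(statusGrid(sm)), c(3, 3))
  ## oracle: classify each window separately
  for (i in 1:3) for (j in 1:3) {
    r0 <- (i - 1) * 30 + 1; c0 <- (j - 1) * 30 + 1
    win <- array(img[r0:(r0 + 29), c0:(c0 + 29), ], c(1, 30, 30, 3))
    p <- predictPatchCnn(m, win)
    expect_equal(statusGrid(sm)[i, j],
                 coralrhythm:::statusCode(colnames(p)[which.max(p)]))
  }
})

test_that("segmentation of a fixture frame agrees with the ground truth", {
  m <- fixtureTrainedModel()
  sc <- generateColonyImage(fixtureSceneSpec(9))
  sm <- segmentFrame(sc$image, m, 30, 10)
  gt <- truthToGrid(sc$truth, 30, 10)
  expect_equal(dim(statusGrid(sm)), dim(statusGrid(gt)))
  agreement <- mean(statusGrid(sm) == statusGrid(gt))
  expect_gte(agreement, 0.85)
  p <- statusPercentages(sm); pt <- statusPercentages(gt)
  expect_lte(abs(p$bloated_pct - pt$bloated_pct), 5)
})

test_that("status percentages follow counting arithmetic and flag empty maps", {
  g <- matrix(c(rep(1L, 300), rep(3L, 100)), 20, 20)
  sm <- new("StatusMap", grid = g, window = 30L, step = 10L)
  p <- statusPercentages(sm)
  expect_equal(c(p$bloated_pct, p$semi_bloated_pct, p$non_bloated_pct),
               c(75, 0, 25))
  expect_false(p$empty)
  empty <- new("StatusMap", grid = matrix(0L, 5, 5), window = 30L,
               step = 10L)
  pe <- statusPercentages(empty)
  expect_true(pe$empty)
  expect_equal(pe$bloated_pct, 0)
  ## invariance to transposition and flips
  for (tr in list(t(g), g[20:1, ], g[, 20:1])) {
    pv <- statusPercentages(new("StatusMap", grid = tr, window = 30L,
                                step = 10L))
    expect_equal(pv$bloated_pct, p$bloated_pct)
    expect_equal(pv$non_bloated_pct, p$non_bloated_pct)
  }
})

test_that("chlorophyll calibration applies the printed day and night formulas", {
  noon <- as.POSIXct("2018-04-23 12:00:00", tz = "UTC")
  midnight <- as.POSIXct("2018-04-23 00:30:00", tz = "UTC")
  expect_equal(calibrateChlorophyll(0, noon), 1.0129)
  expect_equal(calibrateChlorophyll(1, noon), 2.0629)
  expect_equal(calibrateChlorophyll(2, midnight), 2.1419)
  ## boundary: dusk 21:30 is night, 21:29 is day
  dusk <- as.POSIXct("2018-04-23 21:30:00", tz = "UTC")
  expect_equal(calibrateChlorophyll(1, dusk), 0.963 + 0.2159)
  expect_equal(calibrateChlorophyll(1, dusk - 60), 1.050 + 1.0129)
  expect_error(calibrateChlorophyll(-1, noon), ">= 0")
})

test_that("series compilation joins ocean data by nearest time within tolerance", {
  t0 <- as.POSIXct("2018-03-01 11:30:00", tz = "UTC")
  mkFrame <- function(ts, b) list(timestamp = ts,
                                  pct = list(bloated_pct = b,
                                             semi_bloated_pct = 0,
                                             non_bloated_pct = 100 - b,
                                             empty = FALSE))
  frames <- list(mkFrame(t0, 60), mkFrame(t0 + 3600, 40),
                 mkFrame(t0 + 7200, 50))
  ocean <- data.frame(timestamp = c(t0, t0 + 3600 + 600),
                      temperature_C = c(6.5, 6.6),
                      salinity_PSU = c(34.7, 34.8),
                      turbidity_NTU = c(5, 6),
                      chl_fluorescence = c(2, 3), depth_m = c(250, 251))
  s <- compileSeries(frames, ocean, toleranceMin = 30)
  d <- seriesData(s)
  expect_equal(d$temperature_C, c(6.5, 6.6, NA))  # exact, within 10', none
  expect_equal(d$bloated_pct, c(60, 40, 50))
  expect_true(!is.unsorted(d$timestamp))
  ## duplicate frame timestamps rejected
  expect_error(compileSeries(list(mkFrame(t0, 10), mkFrame(t0, 20)), ocean),
               "duplicate")
  ## chlorophyll calibration column when requested
  s2 <- compileSeries(frames, ocean, calibration = chlCalibration())
  expect_equal(seriesData(s2)$chl_a[1], 1.050 * 2 + 1.0129)
})

test_that("a 72-frame fixture chain compiles to 72 monotone rows", {
  t0 <- as.POSIXct("2018-03-01 00:30:00", tz = "UTC")
  frames <- lapply(0:71, function(h)
    list(timestamp = t0 + 3600 * h,
         pct = list(bloated_pct = 50 + 20 * cos(2 * pi * h / 24),
                    semi_bloated_pct = 20,
                    non_bloated_pct = 30 - 20 * cos(2 * pi * h / 24),
                    empty = FALSE)))
  ocean <- seriesData(generateActivitySeries(
    seriesSpec(start = t0, nHours = 72, seed = 3)))
  s <- compileSeries(frames, ocean)
  d <- seriesData(s)
  expect_equal(nrow(d), 72)
  expect_true(all(diff(d$timestamp) > 0))
  expect_true(all(is.finite(d$depth_m)))
})
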