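hourlyTimes <- function(nHours, start = "2018-03-01 00:30:00") {
  as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(nHours) - 1)
}

test_that("a pure cosine is recovered at its injected period with p < 0.05", {
  tt <- hourlyTimes(720)
  tmin <- as.numeric(tt) / 60
  y <- 50 + 20 * cos(2 * pi * tmin / 1440)
  pg <- lombScargle(tt, y)
  pk <- periodogramPeaks(pg)
  expect_gt(nrow(pk), 0)
  expect_lte(abs(pk$period[1] - 1440), 1)
  expect_lt(pk$p[1], 0.05)
  ## noiseless cosine explains essentially all the variance
  expect_gt(pk$power[1], 99)
})

test_that("the periodogram is shift-invariant and quadratic in amplitude", {
  tt <- hourlyTimes(480)
  tmin <- as.numeric(tt) / 60
  mk <- function(A, c0) c0 + A * cos(2 * pi * tmin / 1440) +
    sin(2 * pi * tmin / 300)  # out-of-band clutter
  p1 <- lombScargle(tt, mk(5, 0))
  p2 <- lombScargle(tt, mk(5, 100))
  expect_equal(p1@power, p2@power, tolerance = 1e-9)
  ## raw (un-normalized) explained variance scales with A^2
  v1 <- max(p1@power) / 100 * var(mk(5, 0))
  v4 <- max(lombScargle(tt, mk(10, 0))@power) / 100 * var(mk(10, 0))
  expect_equal(v4 / v1, 4, tolerance = 0.01)
})

test_that("constant and undersampled series hit their error contracts", {
  tt <- hourlyTimes(100)
  pg <- lombScargle(tt, rep(7, 100))
  expect_true(pg@constant)
  expect_true(all(pg@power == 0))
  expect_equal(nrow(periodogramPeaks(pg)), 0)
  expect_error(lombScargle(tt[1:40], rnorm(40)), "48")
  expect_error(lombScargle(rev(tt), rnorm(100)), "increasing")
})

test_that("gaps are handled natively and a lone 24-h rhythm leaves the tidal band empty", {
  tt <- hourlyTimes(720)
  tmin <- as.numeric(tt) / 60
  y <- 50 + 15 * cos(2 * pi * (tmin - 21.5 * 60) / 1440) +
    withSeed(3, rnorm(720, 0, 3))
  y[100:160] <- NA   # sensor gap
  pg <- lombScargle(tt, y)
  pk <- periodogramPeaks(pg)
  expect_lte(abs(pk$period[1] - 1440), 5)
  ## no significant peak in the semidiurnal tidal band (700-800 min)
  tidal <- pk$period >= 700 & pk$period <= 800
  expect_equal(sum(tidal), 0)
})

test_that("white-noise false alarms stay near the nominal level (reduced run)", {
  tt <- hourlyTimes(720)
  nul <- lombScargleNull(tt, nsim = 150, seed = 6)
  expect_lte(nul$rate, 0.10)
})

test_that("waveform analysis satisfies its MESOR algebra", {
  ## constant series: all bins equal, MESOR equal, empty phase
  tt <- hourlyTimes(240)
  wf <- waveformAnalysis(tt, rep(42, 240))
  expect_true(all(wf@mean == 42))
  expect_equal(mesor(wf), 42)
  expect_length(phaseHours(wf), 0)
  ## complete equal-n data: MESOR equals the global mean
  y <- withSeed(4, rnorm(240, 50, 5))
  wf2 <- waveformAnalysis(tt, y)
  expect_equal(mesor(wf2), mean(y))
  expect_equal(sum(wf2@n), 240)
})

test_that("a noiseless dusk-peaking cosine yields a contiguous wrap phase containing hour 21", {
  tt <- hourlyTimes(720)
  tmin <- as.numeric(tt) / 60
  day0 <- as.numeric(as.POSIXct("2018-03-01 00:00:00", tz = "UTC")) / 60
  y <- 50 + 20 * cos(2 * pi * (tmin - (day0 + 21.5 * 60)) / 1440)
  wf <- waveformAnalysis(tt, y)
  expect_true(21 %in% phaseHours(wf))
  iv <- phaseIntervals(wf)
  expect_equal(nrow(iv), 1)            # one contiguous (wrapping) block
  expect_false(iv$singleton[1])
  ## cosine geometry: half the day is above the mean
  expect_equal(iv$n_hours[1], 12)
})

test_that("phase intervals wrap midnight and isolate singletons", {
  mkWf <- function(hours) {
    m <- rep(0, 24); m[hours + 1] <- 1
    new("WaveformResult", hour = 0:23, mean = m, sd = rep(0, 24),
        n = rep(10L, 24), mesor = mean(m), phase = as.integer(hours),
        binMinutes = 60)
  }
  iv <- phaseIntervals(mkWf(c(14:23, 0)))
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start_hour, 14)
  expect_equal(iv$end_hour, 0)
  expect_equal(iv$n_hours, 11)
  iv2 <- phaseIntervals(mkWf(c(2, 3, 4, 13)))
  expect_equal(nrow(iv2), 2)
  expect_equal(iv2$start_hour, c(2, 13))
  expect_equal(iv2$end_hour, c(4, 13))
  expect_equal(iv2$singleton, c(FALSE, TRUE))
  empty <- mkWf(integer(0))
  expect_equal(nrow(phaseIntervals(empty)), 0)
})

test_that("waveform phase recovers the injected peak hour within one bin at SNR 3", {
  for (seed in 1:3) {
    d <- seriesData(generateActivitySeries(
      seriesSpec(nHours = 720, rhythmAmplitude = 15, noiseSd = 5,
                 rhythmPeakHour = 21.5, seed = seed)))
    wf <- waveformAnalysis(d$timestamp, d$bloated_pct)
    iv <- phaseIntervals(wf)
    iv <- iv[!iv$singleton, , drop = FALSE]
    expect_equal(nrow(iv), 1)
    ## circular midpoint of the above-MESOR block (bin centers at HH:30)
    mid <- (iv$start_hour + (iv$n_hours - 1) / 2 + 0.5) %% 24
    dist <- min(abs(mid - 21.5), 24 - abs(mid - 21.5))
    expect_lte(dist, 1)
  }
})

test_that("monthly summaries aggregate by calendar month with missing data excluded", {
  start <- as.POSIXct("2018-02-20 00:30:00", tz = "UTC")
  d <- seriesData(generateActivitySeries(
    seriesSpec(start = start, nHours = 24 * 40, seed = 2)))
  ## inject a known monthly step in turbidity
  mo <- format(d$timestamp, "%Y-%m")
  d$turbidity_NTU <- ifelse(mo == "2018-02", 10, 20)
  d$turbidity_NTU[5] <- NA
  s <- monthlySummary(new("ActivitySeries", data = d))
  tu <- s[s$variable == "turbidity_NTU", ]
  expect_equal(nrow(tu), 2)
  expect_equal(tu$mean, c(10, 20))
  expect_equal(sum(tu$n), nrow(d) - 1)  # the NA is excluded
  ## single-month series gives one row per variable
  d1 <- seriesData(generateActivitySeries(
    seriesSpec(start = as.POSIXct("2018-03-02 00:30:00", tz = "UTC"),
               nHours = 100, seed = 3)))
  s1 <- monthlySummary(new("ActivitySeries", data = d1))
  expect_equal(nrow(s1[s1$variable == "bloated_pct", ]), 1)
})

test_that("the generator-to-periodogram chain flags the injected rhythm only", {
  ## amplitude > 3 * noise: the injected period must be the top peak
  d <- seriesData(generateActivitySeries(
    seriesSpec(nHours = 720, rhythmAmplitude = 20, noiseSd = 4, seed = 8)))
  pg <- lombScargle(d$timestamp, d$bloated_pct)
  expect_lte(abs(periodogramPeaks(pg)$period[1] - 1440), 5)
  ## depth carries the tidal cycle instead
  pgd <- lombScargle(d$timestamp, d$depth_m)
  expect_lte(abs(periodogramPeaks(pgd)$period[1] - 745), 5)
})
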