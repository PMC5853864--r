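test_that("multiresolution details and smooth reconstruct the input", {
  set.seed(40)
  for (filt in c("haar", "d4", "la8")) {
    us <- UniformSeries(cumsum(rnorm(200)), dt = 4)
    d <- mra(us, nLevels = 5, filter = filt)
    recon <- Reduce(`+`, d@details) + d@smooth
    expect_lt(max(abs(recon - seriesValues(us))), 1e-8)
  }
})

test_that("a constant series decomposes into zero details plus itself", {
  d <- mra(UniformSeries(rep(3.5, 64), dt = 4), nLevels = 4)
  for (D in d@details) expect_lt(max(abs(D)), 1e-10)
  expect_equal(d@smooth, rep(3.5, 64), tolerance = 1e-10)
})

test_that("a 48-s sinusoid concentrates in the 32-64 s detail level", {
  us <- sinus_series(256, dt = 4, period = 48)
  d <- mra(us, nLevels = 5)
  energy <- vapply(d@details, function(x) sum(x^2), numeric(1))
  expect_gt(energy[3] / sum(energy), 0.7)
})

test_that("decomposition depth is bounded by the series length", {
  expect_error(mra(UniformSeries(rnorm(40), dt = 1), nLevels = 6), "nLevels")
})

test_that("band selection matches the analysis bands in use", {
  us <- UniformSeries(rnorm(512), dt = 4)
  d <- mra(us, nLevels = 6)
  expect_equal(bandpass(d, 16, 128)$levels, 2:4)    # growth-series band
  expect_equal(bandpass(d, 8, 128)$levels, 1:4)     # spike-analysis band
  expect_error(bandpass(d, 9, 15), "level")
})

test_that("keeping every level plus the trend is the identity", {
  set.seed(41)
  us <- UniformSeries(cumsum(rnorm(128)), dt = 4)
  d <- mra(us, nLevels = 4)
  bp <- bandpass(d, 2 * 4, 2^5 * 4, keepTrend = TRUE)
  expect_lt(max(abs(seriesValues(bp$filtered) - seriesValues(us))), 1e-8)
})

test_that("filtered series plus trend plus excluded noise restores input", {
  set.seed(42)
  us <- UniformSeries(cumsum(rnorm(256)), dt = 4)
  d <- mra(us, nLevels = 5)
  bp <- bandpass(d, 16, 128)
  residual <- seriesValues(us) - seriesValues(bp$filtered) -
    seriesValues(bp$trend)
  # what is left out is exactly the finest detail (the noise band)
  expect_lt(max(abs(residual - d@details[[1]])), 1e-8)
})

test_that("cwt power peaks at the forcing period", {
  us <- sinus_series(256, dt = 4, period = 48)
  sp <- cwt(us)
  peak <- wavePeriods(sp)[which.max(rowMeans(wavePower(sp)))]
  step <- 2^(1 / 12)
  expect_gt(peak, 48 / step)
  expect_lt(peak, 48 * step)
})

test_that("white noise gives a flat time-averaged spectrum at mid scales", {
  spec_mean <- matrix(0, 20, 0)
  avg <- NULL
  for (r in 1:20) {
    set.seed(600 + r)
    sp <- cwt(UniformSeries(rnorm(256), dt = 1))
    m <- rowMeans(wavePower(sp))
    avg <- if (is.null(avg)) m else avg + m
  }
  avg <- avg / 20
  mid <- wavePeriods(sp) > 4 & wavePeriods(sp) < 32
  expect_lt(max(avg[mid]) / min(avg[mid]), 1.5)
})

test_that("doubling the input multiplies power by four", {
  us <- sinus_series(128, dt = 4, period = 48, noiseSd = 0.3)
  us2 <- UniformSeries(2 * seriesValues(us), dt = 4)
  expect_equal(wavePower(cwt(us2)), 4 * wavePower(cwt(us)),
               tolerance = 1e-10)
})

test_that("alpha = 1 marks everything significant", {
  sp <- significance(cwt(sinus_series(64, 4, 48, noiseSd = 1)), alpha = 1)
  expect_true(all(significanceMask(sp)))
})

test_that("an embedded sinusoid is significant at its period almost always", {
  set.seed(44)
  x <- 3 * sin(2 * pi * (0:255) / 32) +
    as.numeric(stats::filter(rnorm(256), 0.5, method = "recursive"))
  sp <- significance(cwt(UniformSeries(x, dt = 1)), 0.05)
  row <- which.min(abs(wavePeriods(sp) - 32))
  ok <- coneOfInfluence(sp) >= 32
  expect_gte(mean(significanceMask(sp)[row, ok]), 0.9)
})

test_that("ridge extraction finds one ridge per time for a pure tone", {
  us <- sinus_series(256, dt = 4, period = 48, noiseSd = 0.05, seed = 2)
  sp <- significance(cwt(us), 0.05)
  r <- extractRidges(sp, maxPerTime = 1)
  pts <- ridgePoints(r)
  counts <- table(pts$time_s)
  expect_true(all(counts == 1))
  inner <- pts[pts$time_s > 200 & pts$time_s < 800, ]
  step <- 2^(1 / 12)
  expect_true(all(inner$period_s > 48 / step & inner$period_s < 48 * step))
  # amplitude estimate recovers the sinusoid amplitude
  expect_equal(median(inner$amplitude), 1, tolerance = 0.15)
})

test_that("two superposed tones give two ridges at both periods", {
  t <- (0:511) * 2
  us <- UniformSeries(sin(2 * pi * t / 20) + sin(2 * pi * t / 60), dt = 2)
  sp <- significance(cwt(us), 0.05)
  pts <- ridgePoints(extractRidges(sp, maxPerTime = 2))
  inner <- pts[pts$time_s > 150 & pts$time_s < 850, ]
  near20 <- abs(log(inner$period_s / 20)) < log(1.2)
  near60 <- abs(log(inner$period_s / 60)) < log(1.2)
  byTime <- split(data.frame(n20 = near20, n60 = near60), inner$time_s)
  both <- vapply(byTime, function(d) any(d$n20) && any(d$n60), logical(1))
  expect_gt(mean(both), 0.9)
})

test_that("series failing significance yield an empty ridge set", {
  us <- ar1_series(64, 0.3, seed = 5)
  sp <- cwt(us)
  sp@signif <- matrix(FALSE, nrow(wavePower(sp)), ncol(wavePower(sp)))
  sp@alpha <- 0.05
  r <- extractRidges(sp)
  expect_equal(nrow(ridgePoints(r)), 0)
  expect_equal(detectionProportion(r), 0)
})

test_that("detection proportion reflects part-time oscillations", {
  # sinusoid in the first half, pure noise after
  n <- 512; t <- (0:(n - 1)) * 4
  set.seed(46)
  v <- ifelse(t < max(t) / 2, sin(2 * pi * t / 48), 0) + rnorm(n, 0, 0.25)
  res <- analyzeOscillations(UniformSeries(v, dt = 4), 16, 128,
                             fixOutliers = FALSE, maxPerTime = 1)
  expect_gt(res$detection, 0.4)
  expect_lt(res$detection, 0.65)
})

test_that("chirp ridges drift monotonically and track the true period", {
  # linear frequency sweep: period 60 s down to 20 s
  n <- 512; dt <- 2
  t <- (0:(n - 1)) * dt
  f0 <- 1 / 60; f1 <- 1 / 20
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * max(t)))
  finst <- f0 + (f1 - f0) * t / max(t)
  us <- UniformSeries(sin(phase), dt = dt)
  sp <- significance(cwt(us), 0.05)
  pts <- ridgePoints(extractRidges(sp, maxPerTime = 1))
  pts <- pts[order(pts$time_s), ]
  inner <- pts[pts$time_s > 100 & pts$time_s < max(t) - 100, ]
  # monotone non-increasing ridge period (small numerical slack)
  expect_true(all(diff(inner$period_s) <= 1e-9))
  trueP <- 1 / finst[match(inner$time_s, t)]
  expect_lt(max(abs(inner$period_s - trueP) / trueP), 0.15)
})

test_that("ridge linking keeps one bout for a tone, splits on gaps", {
  us <- sinus_series(256, dt = 4, period = 48, noiseSd = 0.05, seed = 3)
  sp <- significance(cwt(us), 0.05)
  r <- extractRidges(sp, maxPerTime = 1)
  linked <- linkRidges(r)
  expect_equal(length(unique(linked$bout)), 1)
  # remove a block of times: linking must start a new bout after the gap
  r2 <- r
  r2@points <- r2@points[r2@points$time_s < 400 | r2@points$time_s > 600, ]
  linked2 <- linkRidges(r2)
  expect_equal(length(unique(linked2$bout)), 2)
})
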