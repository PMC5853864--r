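make_trace <- function(pos, dt = 4, dx = 0.22) {
  new("TipTrace", t = (seq_along(pos) - 1) * dt, posPx = pos, dx = dx,
      method = "regression", smoothed = FALSE)
}

test_that("background estimation pools pixels beyond tip + margin", {
  m <- matrix(5, 10, 50)
  k <- Kymograph(m, 4, 0.22, normalize = FALSE)
  be <- estimateBackground(k, make_trace(rep(20, 10)), marginPx = 3)
  expect_equal(backgroundCutoff(be), 5)
  expect_equal(length(be@samples), 10 * (50 - 24))

  # uniform(0, 1) background: 99% quantile ~ 0.99
  set.seed(20)
  m2 <- matrix(runif(100 * 1100), 100, 1100)
  k2 <- Kymograph(m2, 4, 0.22, normalize = FALSE)
  be2 <- estimateBackground(k2, make_trace(rep(50, 100)), marginPx = 3,
                            quantile = 0.99)
  expect_equal(backgroundCutoff(be2), 0.99, tolerance = 0.01)
})

test_that("frames whose tip reaches the last column contribute no samples", {
  m <- matrix(7, 5, 30)
  k <- Kymograph(m, 4, 0.22, normalize = FALSE)
  be <- estimateBackground(k, make_trace(c(10, 10, 29, 10, 10)))
  expect_equal(length(be@samples), 4 * (30 - 14))
  expect_error(estimateBackground(k, make_trace(rep(29, 5))),
               "empty background")
})

test_that("ratio arithmetic, masking, and error cases", {
  y <- Kymograph(matrix(200, 2, 4), 4, 0.22, normalize = FALSE)
  c1 <- Kymograph(matrix(150, 2, 4), 4, 0.22, normalize = FALSE)
  r <- ratioKymograph(y, c1, bgY = 100, bgC = 50)
  expect_true(all(intensityMatrix(r) == 1))
  # denominator at the floor: masked, not divided
  c2 <- Kymograph(matrix(50.5, 2, 4), 4, 0.22, normalize = FALSE)
  r2 <- ratioKymograph(y, c2, bgY = 100, bgC = 50, floor = 1)
  expect_true(all(is.na(intensityMatrix(r2))))
  bad <- Kymograph(matrix(150, 3, 4), 4, 0.22, normalize = FALSE)
  expect_error(ratioKymograph(y, bad, 100, 50), "shape")
})

test_that("noiseless ratiometric pipeline recovers the true ratio field", {
  pair <- simulateRatiometricPair(nFrames = 40, nPx = 120, x0 = 60,
                                  noiseSd = 0)
  rk <- ratioKymograph(pair$yfp, pair$cfp, pair$truth$bgY, pair$truth$bgC,
                       floor = 1)
  ok <- !is.na(rk@values)
  expect_lt(max(abs(rk@values - pair$truth$ratioField)[ok]), 1e-9)
})

test_that("channel-specific cutoffs track distinct background levels", {
  pair <- simulateRatiometricPair(nFrames = 60, nPx = 160, x0 = 100,
                                  bgY = 20, bgC = 10, noiseSd = 2, seed = 6)
  tr <- traceTip(strongestChannel(pair$yfp, pair$cfp))
  bgY <- estimateBackground(pair$yfp, tr)
  bgC <- estimateBackground(pair$cfp, tr)
  expect_gt(backgroundCutoff(bgY), backgroundCutoff(bgC))
  expect_equal(backgroundCutoff(bgY) - backgroundCutoff(bgC), 10,
               tolerance = 2)
})

test_that("background and signal distributions separate at SNR 10", {
  sim <- simulateKymograph(nFrames = 80, nPx = 200, x0 = 120, seed = 8)
  tr <- traceTip(sim$kymo)
  be <- estimateBackground(sim$kymo, tr)
  inside <- intensityMatrix(sim$kymo)[, 1:80]   # deep inside the cell
  overlap <- mean(inside < backgroundCutoff(be))
  expect_lt(overlap, 0.01)
  expect_gt(backgroundCutoff(be), sim$truth$bg)
  expect_lt(backgroundCutoff(be), sim$truth$plateau / 2)
})

test_that("alignment leaves constant profiles constant", {
  m <- matrix(3, 6, 40)
  ak <- alignToTip(Kymograph(m, 4, 0.22, normalize = FALSE),
                   make_trace(20 + 0.3 * (0:5)))
  vals <- intensityMatrix(ak)
  expect_true(all(vals[!is.na(vals)] == 3))
})

test_that("integer traces with dx = 1 reduce alignment to an index shift", {
  set.seed(21)
  m <- matrix(rnorm(5 * 30), 5, 30)
  pos <- c(10, 12, 11, 13, 10)
  ak <- alignToTip(Kymograph(m, 4, 1, normalize = FALSE), make_trace(pos, dx = 1))
  for (f in 1:5) {
    shifted <- m[f, (pos[f] + 1):1]
    got <- intensityMatrix(ak)[f, seq_along(shifted)]
    expect_equal(got, shifted, tolerance = 1e-12)
  }
})

test_that("the tip bump stays in the distance-0 column despite tip motion", {
  sim <- simulateKymograph(nFrames = 60, nPx = 150, x0 = 60, noiseSd = 0,
                           bumpHeight = 60, bumpSd = 2)
  truthTrace <- make_trace(sim$truth$tipPx)
  ak <- alignToTip(sim$kymo, truthTrace)
  # the bump peaks just inside the apex; after alignment that column is
  # elevated and steady in every frame despite the moving tip
  prof <- colMeans(intensityMatrix(ak), na.rm = TRUE)
  peakUm <- distanceGrid(ak)[which.max(prof)]
  expect_lt(peakUm, 1)
  atBump <- intensityMatrix(ak)[, which.max(prof)]
  inside <- extractRegionSeries(ak, 5, 0.44, stat = "mean")
  expect_true(all(atBump > seriesValues(inside)))
  expect_lt(sd(atBump), 1)               # bump held in place across frames
})

test_that("region extraction: single column, constants, tip vs shank", {
  m <- matrix(2.5, 8, 120)
  ak <- alignToTip(Kymograph(m, 4, 0.22, normalize = FALSE),
                   make_trace(rep(100, 8)))
  one <- extractRegionSeries(ak, 2.2, 0.1)     # narrower than a pixel
  expect_equal(length(one), 8)
  expect_true(all(seriesValues(one) == 2.5))

  pair <- simulateRatiometricPair(nFrames = 40, nPx = 200, x0 = 120,
                                  noiseSd = 0)
  tr <- traceTip(pair$yfp)
  rk <- ratioKymograph(pair$yfp, pair$cfp, pair$truth$bgY, pair$truth$bgC)
  ak2 <- alignToTip(rk, tr)
  tipS <- extractRegionSeries(ak2, 2.2, 1.1)
  shankS <- extractRegionSeries(ak2, 19.4, 1.1)
  expect_true(all(seriesValues(tipS) > seriesValues(shankS)))
  g <- tipShankGradient(tipS, shankS)
  expect_equal(mean(seriesValues(g)), 0.4, tolerance = 0.12)
})

test_that("tip/shank gradient arithmetic and error cases", {
  a <- RawSeries(0:4, rep(2, 5)); b <- RawSeries(0:4, rep(1, 5))
  expect_true(all(seriesValues(tipShankGradient(a, a)) == 0))
  expect_true(all(seriesValues(tipShankGradient(a, b)) == 1))
  neg <- RawSeries(0:4, c(1, 1, 0, 1, 1))
  expect_error(tipShankGradient(a, neg), "positive")
})

test_that("scans along the tube return one series per centre", {
  m <- matrix(4, 10, 150)
  ak <- alignToTip(Kymograph(m, 4, 0.22, normalize = FALSE),
                   make_trace(rep(120, 10)))
  sc <- scanSeriesAlongTube(ak, 1.5, 21.5, 1.5, 1.1)
  expect_length(sc, length(seq(1.5, 21.5, 1.5)))
  for (s in sc) expect_true(all(seriesValues(s) == 4))
  expect_error(scanSeriesAlongTube(ak, 5, 2), "startUm")
})
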