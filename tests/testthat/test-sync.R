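test_that("matching identical series returns identical outputs", {
  set.seed(50)
  t <- (0:199) * 4
  rs <- RawSeries(t, sin(2 * pi * t / 48) + rnorm(200, 0, 0.1))
  m <- matchSeries(rs, rs, dtTarget = 4)
  expect_equal(seriesValues(m$a), seriesValues(m$b))
  expect_equal(m$a@t0, m$b@t0)
})

test_that("series at different rates meet on a common grid", {
  t1 <- (0:199) * 4
  t2 <- (0:159) * 5
  a <- RawSeries(t1, sin(2 * pi * t1 / 48))
  b <- RawSeries(t2, sin(2 * pi * t2 / 48))
  m <- matchSeries(a, b, dtTarget = 4)
  expect_equal(m$a@dt, 4)
  expect_equal(m$b@dt, 4)
  expect_equal(length(m$a), length(m$b))
  expect_lte(max(sampleTimes(m$a)), min(max(t1), max(t2)))
})

test_that("matching preserves an injected lag (cross-correlation oracle)", {
  sim <- simulateSeriesPair(n = 256, dt = 4, period = 48, lag = 8,
                            noiseSd = 0.1, seed = 7)
  m <- matchSeries(sim$x, sim$y, dtTarget = 4)
  x <- seriesValues(m$a); y <- seriesValues(m$b)
  lags <- -6:6
  cc <- vapply(lags, function(L) {
    idx <- seq_len(length(x) - abs(L))
    if (L >= 0) cor(x[idx], y[idx + L]) else cor(x[idx - L], y[idx])
  }, numeric(1))
  expect_equal(lags[which.max(cc)] * 4, 8)
})

test_that("too-short overlaps are refused", {
  a <- RawSeries((0:40) * 4, rnorm(41))
  b <- RawSeries((25:60) * 4, rnorm(36))
  expect_error(matchSeries(a, b, dtTarget = 4), "32")
  expect_error(matchSeries(a, RawSeries((200:240) * 4, rnorm(41))),
               "overlap")
})

test_that("self cross-spectrum has zero phase and squared power", {
  us <- sinus_series(128, dt = 4, period = 48, noiseSd = 0.2, seed = 8)
  xs <- xwt(us, us)
  expect_true(all(abs(phaseMatrix(xs)) < 1e-12))
  expect_equal(wavePower(xs), wavePower(cwt(us)), tolerance = 1e-10)
})

test_that("a quarter-cycle delay appears as phase +pi/2 at the period", {
  t <- (0:255) * 4
  a <- UniformSeries(sin(2 * pi * t / 48), dt = 4)
  b <- UniformSeries(sin(2 * pi * (t - 12) / 48), dt = 4)
  xs <- xwt(a, b)
  row <- which.min(abs(wavePeriods(xs) - 48))
  inner <- t > 200 & t < 800
  expect_equal(median(phaseMatrix(xs)[row, inner]), pi / 2,
               tolerance = 0.05)
})

test_that("cross-wavelet significance is calibrated on independent noise", {
  fr <- vapply(1:20, function(r) {
    a <- ar1_series(256, 0.5, seed = 700 + r)
    b <- ar1_series(256, 0.5, seed = 900 + r)
    xs <- significance(xwt(a, b), 0.05)
    trust <- outer(wavePeriods(xs), coneOfInfluence(xs), `<=`)
    mean(significanceMask(xs)[trust])
  }, numeric(1))
  expect_gt(mean(fr), 0.02)
  expect_lt(mean(fr), 0.08)
})

test_that("phase-to-delay arithmetic follows the sign convention", {
  r <- new("RidgeSet",
           points = data.frame(time_s = c(0, 4), period_s = c(48, 48),
                               power = c(1, 1), amplitude = c(1, 1),
                               phase = c(0, pi / 2)),
           maxPerTime = 1, times = c(0, 4), coiTimes = c(TRUE, TRUE))
  xs <- new("CrossSpectrum", xpower = matrix(1, 1, 2),
            phase = matrix(0, 1, 2), wave = matrix(1 + 0i, 1, 2),
            periods = 48, scales = 48, times = c(0, 4), coi = c(99, 99),
            ar1 = c(0, 0), sigma2 = c(1, 1))
  d <- phaseToDelay(xs, r)
  expect_equal(d$delay_s, c(0, 12))   # phase pi/2 at 48 s leads by 12 s
})

test_that("injected lags are recovered and swapping inputs negates them", {
  for (lag in c(0, 2, 4, 8, 12)) {
    sim <- simulateSeriesPair(n = 256, dt = 4, period = 48, amp = 1,
                              lag = lag, ar1 = 0.3, noiseSd = 1 / 3,
                              seed = 3)
    m <- matchSeries(sim$x, sim$y, dtTarget = 4)
    xs <- significance(xwt(m$a, m$b, nullA = m$prepA, nullB = m$prepB),
                       0.05)
    d <- phaseToDelay(xs, extractRidges(xs, maxPerTime = 1))
    expect_lt(abs(median(d$delay_s) - lag), 2)            # within dt/2
    xsSwap <- significance(xwt(m$b, m$a, nullA = m$prepB, nullB = m$prepA),
                           0.05)
    expect_equal(phaseMatrix(xsSwap), -phaseMatrix(xs), tolerance = 1e-10)
    dSwap <- phaseToDelay(xsSwap, extractRidges(xsSwap, maxPerTime = 1))
    expect_equal(median(dSwap$delay_s), -median(d$delay_s),
                 tolerance = 1e-6)
  }
})

test_that("a mid-series lag sign flip is localized", {
  n <- 300; dt <- 4
  t <- (0:(n - 1)) * dt
  set.seed(52)
  x <- sin(2 * pi * t / 48) + rnorm(n, 0, 0.2)
  lagv <- ifelse(t < t[150], -8, 8)
  y <- sin(2 * pi * (t - lagv) / 48) + rnorm(n, 0, 0.2)
  m <- matchSeries(RawSeries(t, x, collapse = FALSE),
                   RawSeries(t, y, collapse = FALSE), dtTarget = 4)
  xs <- significance(xwt(m$a, m$b, nullA = m$prepA, nullB = m$prepB), 0.05)
  d <- phaseToDelay(xs, extractRidges(xs, maxPerTime = 1))
  d <- d[order(d$time_s), ]
  crossings <- d$time_s[which(diff(sign(d$delay_s)) != 0)]
  # localized within two 120-s windows of the true change point
  expect_true(any(abs(crossings - t[150]) <= 240))
  expect_lt(median(d$delay_s[d$time_s < t[150] - 60]), 0)
  expect_gt(median(d$delay_s[d$time_s > t[150] + 60]), 0)
})

test_that("phase histogram summarizes concentration correctly", {
  mk <- function(phases) new("RidgeSet",
    points = data.frame(time_s = seq_along(phases), period_s = 48,
                        power = 1, amplitude = 1, phase = phases),
    maxPerTime = 1, times = seq_along(phases),
    coiTimes = rep(TRUE, length(phases)))
  xs <- new("CrossSpectrum", xpower = matrix(1, 1, 2),
            phase = matrix(0, 1, 2), wave = matrix(1 + 0i, 1, 2),
            periods = 48, scales = 48, times = c(0, 4), coi = c(99, 99),
            ar1 = c(0, 0), sigma2 = c(1, 1))
  allZero <- phaseHistogram(xs, mk(rep(0, 50)))
  expect_equal(allZero$R, 1)
  expect_equal(allZero$mean, 0)
  set.seed(53)
  unif <- phaseHistogram(xs, mk(runif(1000, -pi, pi)))
  expect_lt(unif$R, 0.1)
  expect_error(phaseHistogram(xs, mk(rep(0, 5))), "10")
  # lagged sinusoid pair: circular mean within one bin of 2 pi lag / period
  sim <- simulateSeriesPair(n = 256, dt = 4, period = 48, lag = 4,
                            ar1 = 0.3, noiseSd = 0.3, seed = 3)
  m <- matchSeries(sim$x, sim$y, dtTarget = 4)
  xsr <- significance(xwt(m$a, m$b, nullA = m$prepA, nullB = m$prepB), 0.05)
  ph <- phaseHistogram(xsr, extractRidges(xsr, maxPerTime = 1))
  expect_lt(abs(ph$mean - 2 * pi * 4 / 48), 2 * pi / 16)
})

test_that("synchrony flags separate locked, noisy, and slipping pairs", {
  set.seed(54)
  us <- UniformSeries(sin(2 * pi * (0:255) * 4 / 48) + rnorm(256, 0, 0.2),
                      dt = 4)
  xs <- significance(xwt(us, us), 0.05)
  sf <- synchronyFlag(xs, extractRidges(xs, maxPerTime = 1), window = 240)
  expect_true(all(sf$synchronized))

  noise <- vapply(1:5, function(s) {
    sim <- simulateSeriesPair(n = 256, dt = 4, amp = 0, ar1 = 0.5,
                              noiseSd = 1, seed = 100 + s)
    m <- matchSeries(sim$x, sim$y, dtTarget = 4)
    xsI <- significance(xwt(m$a, m$b, nullA = m$prepA, nullB = m$prepB),
                        0.05)
    mean(synchronyFlag(xsI, extractRidges(xsI, maxPerTime = 1),
                       window = 240)$synchronized)
  }, numeric(1))
  expect_lt(mean(noise), 0.1)

  # 10% period mismatch: phase slips through the full circle
  n <- 300; t <- (0:(n - 1)) * 4
  set.seed(55)
  slip <- matchSeries(
    RawSeries(t, sin(2 * pi * t / 48) + rnorm(n, 0, 0.15), collapse = FALSE),
    RawSeries(t, sin(2 * pi * t / 52.8) + rnorm(n, 0, 0.15),
              collapse = FALSE), dtTarget = 4)
  xsS <- significance(xwt(slip$a, slip$b, nullA = slip$prepA,
                          nullB = slip$prepB), 0.05)
  sfS <- synchronyFlag(xsS, extractRidges(xsS, maxPerTime = 1),
                       window = 240, tol = 0.3)
  expect_equal(mean(sfS$synchronized), 0)
})
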