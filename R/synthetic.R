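#' Synthetic kymographs and series with known ground truth
#'
#' The generators emulate the data this pipeline targets: a bright cell
#' region ending in a sigmoidal edge over dark background, a tip trajectory
#' with linear trend plus sinusoidal oscillation, paired spectrally
#' co-registered channels with distinct backgrounds, additive noise,
#' photobleaching drift, occasional outliers, and series pairs sharing a
#' period with a fixed lag. All generators are pure functions of their
#' parameters and seed, and return ground truth sufficient to score every
#' downstream estimator.
#'
#' @name synthetic
NULL

logistic <- function(u) 1 / (1 + exp(-u))

.tip_trajectory <- function(nFrames, dt, dx, v, period, amp, x0) {
  t <- (seq_len(nFrames) - 1) * dt
  x0 + (v / 60) * t / dx + (amp / dx) * sin(2 * pi * t / period)
}

#' Simulate a single-channel kymograph
#'
#' The tip follows \code{x(t) = x0 + (v/60) t/dx + (amp/dx) sin(2 pi t /
#' period)} (pixels, 0-based grid). Each frame's profile is a logistic edge
#' from a (photobleaching) plateau down to the background level, plus
#' optional tip-focused Gaussian intensity bump and additive Gaussian noise.
#'
#' @param nFrames,nPx frames (time) and pixels (space).
#' @param dt frame interval, s. Default 4.
#' @param dx pixel size, um. Default 0.22.
#' @param v mean growth rate, um/min. Default 2.
#' @param period oscillation period, s. Default 48.
#' @param amp position oscillation amplitude, um. Default 0.25.
#' @param edgeWidth logistic edge width, px. Default 1 (a diffraction-
#'   limited edge at ~0.22 um/px sampling).
#' @param plateau,bgLevel cell and background intensity. Defaults 100 and 10.
#' @param noiseSd additive Gaussian noise sd. Default 9 (SNR 10).
#' @param bleachRate exponential intensity decay per frame. Default 0.
#' @param bumpHeight,bumpSd optional tip-focused intensity bump (height,
#'   Gaussian sd in px). Default no bump.
#' @param x0 initial tip position, px. Default \code{0.25 * nPx}.
#' @param seed RNG seed.
#' @return list with \code{kymo} (a [Kymograph-class]) and \code{truth}
#'   (list: \code{tipPx}, \code{t}, \code{periodS}, \code{ampUm},
#'   \code{vUmMin}, \code{bg}, \code{plateau}).
#' @export
simulateKymograph <- function(nFrames = 300, nPx = 200, dt = 4, dx = 0.22,
                              v = 2, period = 48, amp = 0.25,
                              edgeWidth = 1, plateau = 100, bgLevel = 10,
                              noiseSd = 9, bleachRate = 0,
                              bumpHeight = 0, bumpSd = 3,
                              x0 = 0.25 * nPx, seed = 1) {
  stopifnot(plateau > bgLevel, edgeWidth >= 1, period > 2 * dt)
  x <- .tip_trajectory(nFrames, dt, dx, v, period, amp, x0)
  if (any(x < 0 | x > nPx - 1))
    stop("tip trajectory leaves the field of view")
  p <- seq_len(nPx) - 1
  clean <- matrix(0, nFrames, nPx)
  for (f in seq_len(nFrames)) {
    top <- plateau * exp(-bleachRate * (f - 1))
    prof <- bgLevel + (top - bgLevel) * logistic((x[f] - p) / edgeWidth)
    if (bumpHeight > 0)
      prof <- prof + bumpHeight * exp(-(p - x[f])^2 / (2 * bumpSd^2)) *
        logistic((x[f] - p) / edgeWidth)
    clean[f, ] <- prof
  }
  vals <- clean
  if (noiseSd > 0) {
    set.seed(seed)
    vals <- vals + matrix(stats::rnorm(nFrames * nPx, 0, noiseSd),
                          nFrames, nPx)
  }
  list(kymo = Kymograph(vals, dt = dt, dx = dx, channel = "synthetic",
                        normalize = FALSE),
       truth = list(tipPx = x, t = (seq_len(nFrames) - 1) * dt,
                    periodS = period, ampUm = amp, vUmMin = v,
                    bg = bgLevel, plateau = plateau, clean = clean))
}

#' Simulate a co-registered YFP/CFP ratiometric kymograph pair
#'
#' Both channels share the tip geometry; the YFP signal is constructed as
#' \code{bgY + ratioField * (CFP_clean - bgC)} so that the background-
#' subtracted ratio recovers \code{ratioField} exactly in the noiseless
#' case. The true ratio decays linearly from \code{ratioTip} at the tip to
#' \code{ratioShank} at \code{gradLengthUm} into the cell (a tip-focused
#' gradient).
#'
#' @inheritParams simulateKymograph
#' @param ratioTip,ratioShank true ratio at the tip and in the shank.
#'   Defaults 1.5 and 1.0.
#' @param gradLengthUm distance over which the ratio decays, um. Default 10.
#' @param bgY,bgC channel background levels (may differ). Defaults 20, 10.
#' @param plateauC CFP plateau intensity. Default 100.
#' @return list with \code{yfp}, \code{cfp} ([Kymograph-class]) and
#'   \code{truth} (adds \code{ratioField}, \code{bgY}, \code{bgC}).
#' @export
simulateRatiometricPair <- function(nFrames = 200, nPx = 200, dt = 4,
                                    dx = 0.22, v = 2, period = 48,
                                    amp = 0.25, edgeWidth = 1,
                                    plateauC = 100, bgY = 20, bgC = 10,
                                    ratioTip = 1.5, ratioShank = 1.0,
                                    gradLengthUm = 10, noiseSd = 0,
                                    bleachRate = 0, x0 = 0.25 * nPx,
                                    seed = 1) {
  stopifnot(plateauC > bgC, edgeWidth >= 1)
  x <- .tip_trajectory(nFrames, dt, dx, v, period, amp, x0)
  if (any(x < 0 | x > nPx - 1))
    stop("tip trajectory leaves the field of view")
  p <- seq_len(nPx) - 1
  cfpClean <- matrix(0, nFrames, nPx)
  ratioField <- matrix(NA_real_, nFrames, nPx)
  for (f in seq_len(nFrames)) {
    top <- plateauC * exp(-bleachRate * (f - 1))
    cfpClean[f, ] <- bgC + (top - bgC) * logistic((x[f] - p) / edgeWidth)
    d <- (x[f] - p) * dx               # distance from tip into the cell, um
    r <- ratioShank + (ratioTip - ratioShank) *
      pmax(0, 1 - pmax(d, 0) / gradLengthUm)
    ratioField[f, ] <- r
  }
  yfpClean <- bgY + ratioField * (cfpClean - bgC)
  yfp <- yfpClean; cfp <- cfpClean
  if (noiseSd > 0) {
    set.seed(seed)
    yfp <- yfp + matrix(stats::rnorm(nFrames * nPx, 0, noiseSd), nFrames, nPx)
    cfp <- cfp + matrix(stats::rnorm(nFrames * nPx, 0, noiseSd), nFrames, nPx)
  }
  list(yfp = Kymograph(yfp, dt = dt, dx = dx, channel = "YFP",
                       normalize = FALSE),
       cfp = Kymograph(cfp, dt = dt, dx = dx, channel = "CFP",
                       normalize = FALSE),
       truth = list(tipPx = x, t = (seq_len(nFrames) - 1) * dt,
                    periodS = period, ampUm = amp, vUmMin = v,
                    bgY = bgY, bgC = bgC, ratioField = ratioField))
}

#' Simulate a lagged pair of oscillating time series
#'
#' \code{x(t) = trend(t) + amp sin(2 pi t / period) + AR(1) noise};
#' \code{y(t)} is the same sinusoid delayed by \code{lag} seconds plus
#' independent AR(1) noise (no trend). Optional additive outliers are
#' injected into \code{x} at seeded positions, half adding and half
#' subtracting \code{outlierMag}.
#'
#' @param n number of samples.
#' @param dt sampling interval, s.
#' @param period oscillation period, s.
#' @param amp oscillation amplitude.
#' @param lag delay of the second series behind the first, s
#'   (\code{lag < period}).
#' @param ar1 AR(1) coefficient of the noise, |ar1| < 1.
#' @param noiseSd stationary sd of the AR(1) noise.
#' @param nOutliers number of additive outliers injected into x.
#' @param outlierMag outlier magnitude (added as +/- outlierMag).
#' @param trend polynomial coefficients of the trend in x, constant first
#'   (e.g. \code{c(0, 0.01)} for a linear drift per second).
#' @param seed RNG seed.
#' @return list with \code{x}, \code{y} ([RawSeries-class]) and \code{truth}
#'   (clean series, outlier indices/signs, \code{lag}, \code{period}).
#' @export
simulateSeriesPair <- function(n = 256, dt = 4, period = 48, amp = 1,
                               lag = 0, ar1 = 0.3, noiseSd = 0.2,
                               nOutliers = 0, outlierMag = 10,
                               trend = c(0), seed = 1) {
  stopifnot(abs(ar1) < 1, lag < period)
  t <- (seq_len(n) - 1) * dt
  trendv <- rowSums(outer(t, seq_along(trend) - 1, `^`) *
                      rep(trend, each = n))
  sx <- amp * sin(2 * pi * t / period)
  sy <- amp * sin(2 * pi * (t - lag) / period)
  set.seed(seed)
  arNoise <- function() {
    if (noiseSd == 0) return(numeric(n))
    e <- stats::rnorm(n, 0, noiseSd * sqrt(1 - ar1^2))
    as.numeric(stats::filter(e, ar1, method = "recursive"))
  }
  xClean <- trendv + sx
  x <- xClean + arNoise()
  y <- sy + arNoise()
  outIdx <- integer(0); outSign <- numeric(0)
  if (nOutliers > 0) {
    outIdx <- sort(sample(seq(5, n - 4), nOutliers))
    outSign <- rep(c(1, -1), length.out = nOutliers)
    x[outIdx] <- x[outIdx] + outSign * outlierMag
  }
  list(x = RawSeries(t, x, collapse = FALSE),
       y = RawSeries(t, y, collapse = FALSE),
       truth = list(t = t, xClean = xClean, yClean = sy,
                    xNoOutlier = x - {
                      z <- numeric(n); z[outIdx] <- outSign * outlierMag; z
                    },
                    outlierIndex = outIdx, outlierSign = outSign,
                    lag = lag, period = period, trend = trendv))
}
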