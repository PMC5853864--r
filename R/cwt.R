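#' Continuous Morlet wavelet spectrum
#'
#' Morlet continuous wavelet transform on log-spaced scales, with the
#' standard conventions: scales \code{s0 * 2^(j*dj)}, Fourier-equivalent
#' periods, e-folding cone of influence, and a pointwise red-noise
#' (lag-1 autoregressive) chi-squared significance test.
#'
#' @name cwt-module
NULL

.fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Continuous wavelet transform of a uniform series
#'
#' The series is demeaned and zero-padded to the next power of two (edge
#' effects are made explicit by the cone of influence). The lag-1
#' autocorrelation of the linearly detrended input is estimated and stored
#' for the significance test.
#'
#' @param us a [UniformSeries-class] with \code{n >= 32}; detrending /
#'   band-filtering is the caller's duty (see [bandFilter()]).
#' @param dj scale resolution in octaves^-1 (default 1/12).
#' @param s0 smallest scale, seconds (default \code{2 * dt}).
#' @param J number of scales above s0 (default: spanning periods up to
#'   \code{n * dt / 4}).
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @param null optional [UniformSeries-class] from which the red-noise null
#'   (lag-1 autocorrelation and variance) is estimated instead of the input
#'   — pass the series as it was before band filtering: a null fitted to a
#'   band-filtered series mistakes the filter's passband for signal.
#' @return a [CwtSpectrum-class] (significance mask empty until
#'   [significance()]).
#' @export
cwt <- function(us, dj = 1 / 12, s0 = NULL, J = NULL, omega0 = 6,
                null = NULL) {
  stopifnot(is(us, "UniformSeries"))
  x <- us@v
  n <- length(x)
  if (n < 32L) stop("need at least 32 samples")
  dt <- us@dt
  if (is.null(s0)) s0 <- 2 * dt
  ff <- .fourier_factor(omega0)
  if (is.null(J)) {
    smax <- n * dt / 4 / ff
    J <- max(1L, floor(log2(smax / s0) / dj))
  }
  scales <- s0 * 2^((0:J) * dj)
  periods <- ff * scales
  xd <- x - mean(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(xd, numeric(npad - n))
  xh <- stats::fft(xp) / npad
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                  -2 * pi * (npad - k) / (npad * dt))
  wave <- matrix(0 + 0i, length(scales), n)
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-(s * omega - omega0)^2 / 2) * (omega > 0)
    wave[i, ] <- stats::fft(xh * psi, inverse = TRUE)[seq_len(n)]
  }
  dedge <- pmin(seq_len(n) - 1, n - seq_len(n))
  coi <- ff * sqrt(2) * dt * pmax(dedge, 1e-8)
  # red-noise null: lag-1 autocorrelation after linear detrending
  xn <- if (is.null(null)) x else null@v
  nn <- length(xn)
  z <- stats::residuals(stats::lm(xn ~ seq_len(nn)))
  ar1 <- sum(z[-1] * z[-nn]) / sum(z^2)
  new("CwtSpectrum", power = abs(wave)^2, wave = wave, periods = periods,
      scales = scales, times = sampleTimes(us), coi = coi,
      ar1 = ar1, sigma2 = stats::var(z), omega0 = omega0)
}

# theoretical red-noise spectrum at frequency f (cycles per sample)
.rednoise_spectrum <- function(ar1, f) {
  (1 - ar1^2) / (1 + ar1^2 - 2 * ar1 * cos(2 * pi * f))
}

#' @describeIn significance pointwise chi-squared test of single-series
#'   power against the variance-matched AR(1) red-noise spectrum: the null
#'   model in which the process depends only on its previous state.
#' @export
setMethod("significance", "CwtSpectrum", function(spec, alpha = 0.05) {
  dt <- diff(spec@times[1:2])
  f <- dt / spec@periods
  pk <- .rednoise_spectrum(spec@ar1, f)
  level <- spec@sigma2 * pk * stats::qchisq(1 - alpha, df = 2) / 2
  spec@signif <- sweep(spec@power, 1, level, `>`)
  spec@alpha <- alpha
  spec
})

.trustworthy <- function(periods, coi) {
  # TRUE where the period is below the cone of influence (reliable region)
  outer(periods, coi, `<=`)
}

.morlet_amplitude <- function(power, scales, dt) {
  # sinusoid amplitude implied by |W|^2 at its matching scale under the
  # sqrt(2 pi s / dt) normalization
  2 * sqrt(power) * pi^(1 / 4) / sqrt(2 * pi * scales / dt)
}

.ridge_points <- function(power, phase, periods, scales, times, coi, signif,
                          minPowerFrac, maxPerTime, dt) {
  ok <- .trustworthy(periods, coi) & signif
  pmax_global <- suppressWarnings(max(power[ok]))
  if (!is.finite(pmax_global))
    pmax_global <- Inf                    # nothing significant anywhere
  nS <- length(periods)
  rows <- vector("list", length(times))
  for (ti in seq_along(times)) {
    p <- power[, ti]
    # local maxima along the period axis
    locmax <- which(diff(sign(diff(c(-Inf, p, -Inf)))) < 0)
    cand <- locmax[ok[locmax, ti] & p[locmax] >= minPowerFrac * pmax_global]
    if (length(cand) == 0L) next
    cand <- cand[order(p[cand], decreasing = TRUE)]
    cand <- cand[seq_len(min(maxPerTime, length(cand)))]
    amp <- .morlet_amplitude(p[cand], scales[cand], dt)
    df <- data.frame(time_s = times[ti], period_s = periods[cand],
                     power = p[cand], amplitude = amp)
    if (!is.null(phase)) df$phase <- phase[cand, ti]
    rows[[ti]] <- df
  }
  pts <- do.call(rbind, rows)
  if (is.null(pts))
    pts <- data.frame(time_s = numeric(0), period_s = numeric(0),
                      power = numeric(0), amplitude = numeric(0))
  pts
}

#' @describeIn extractRidges per-time local maxima of single-series power,
#'   restricted to significant cells outside the cone of influence.
#' @export
setMethod("extractRidges", "CwtSpectrum",
  function(spec, minPowerFrac = 0.05, maxPerTime = 2) {
    if (is.na(spec@alpha))
      stop("run significance() before extracting ridges")
    dt <- diff(spec@times[1:2])
    pts <- .ridge_points(spec@power, NULL, spec@periods, spec@scales,
                         spec@times, spec@coi, spec@signif,
                         minPowerFrac, maxPerTime, dt)
    new("RidgeSet", points = pts, maxPerTime = maxPerTime,
        times = spec@times, coiTimes = spec@coi >= min(spec@periods))
  })

#' @describeIn extractRidges ridges of cross power; each point also carries
#'   the local phase difference.
#' @export
setMethod("extractRidges", "CrossSpectrum",
  function(spec, minPowerFrac = 0.05, maxPerTime = 2) {
    if (is.na(spec@alpha))
      stop("run significance() before extracting ridges")
    dt <- diff(spec@times[1:2])
    pts <- .ridge_points(spec@xpower, spec@phase, spec@periods, spec@scales,
                         spec@times, spec@coi, spec@signif,
                         minPowerFrac, maxPerTime, dt)
    new("RidgeSet", points = pts, maxPerTime = maxPerTime,
        times = spec@times, coiTimes = spec@coi >= min(spec@periods))
  })

#' Proportion of time with a detected oscillation
#'
#' The fraction of time points in the trustworthy region (some period below
#' the cone of influence) carrying at least one ridge: the proportion of
#' time a significant periodic component is present in the spectrum.
#'
#' @param ridges a [RidgeSet-class].
#' @return a fraction in [0, 1].
#' @export
detectionProportion <- function(ridges) {
  stopifnot(is(ridges, "RidgeSet"))
  inside <- ridges@times[ridges@coiTimes]
  if (length(inside) == 0L) return(0)
  detected <- unique(ridges@points$time_s)
  length(intersect(detected, inside)) / length(inside)
}

#' Link ridge points into oscillatory bouts
#'
#' Greedy nearest-period matching between consecutive time points, with a
#' maximum jump of \code{maxJumpSteps} scale steps; maximal linked runs are
#' bouts (e.g. single bouts of spikes).
#'
#' @param ridges a [RidgeSet-class].
#' @param dj scale resolution used in the transform (default 1/12).
#' @param maxJumpSteps maximum period jump between consecutive times, in
#'   scale steps (default 2).
#' @return the ridge table with an added integer \code{bout} column.
#' @export
linkRidges <- function(ridges, dj = 1 / 12, maxJumpSteps = 2) {
  pts <- ridges@points
  if (nrow(pts) == 0L) {
    pts$bout <- integer(0)
    return(pts)
  }
  pts <- pts[order(pts$time_s, -pts$power), ]
  pts$bout <- NA_integer_
  maxLogJump <- maxJumpSteps * dj * log(2)
  gridStep <- if (length(ridges@times) > 1L) min(diff(ridges@times)) else Inf
  nextBout <- 1L
  prevIdx <- integer(0)
  prevTime <- -Inf
  for (tv in unique(pts$time_s)) {
    cur <- which(pts$time_s == tv)
    if (tv - prevTime > 1.5 * gridStep) prevIdx <- integer(0)
    prevTime <- tv
    used <- logical(length(prevIdx))
    for (i in cur) {
      if (length(prevIdx) > 0L) {
        dlog <- abs(log(pts$period_s[i]) - log(pts$period_s[prevIdx]))
        dlog[used] <- Inf
        j <- which.min(dlog)
        if (length(j) == 1L && is.finite(dlog[j]) && dlog[j] <= maxLogJump) {
          pts$bout[i] <- pts$bout[prevIdx[j]]
          used[j] <- TRUE
          next
        }
      }
      pts$bout[i] <- nextBout
      nextBout <- nextBout + 1L
    }
    prevIdx <- cur
  }
  pts
}
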