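#' One-call oscillation analysis of a uniform series
#'
#' The standard analysis chain for a prepared series: outlier
#' detection/restoration ([removeOutliers()]), multiresolution band
#' filtering ([bandFilter()]), continuous wavelet spectrum ([cwt()]),
#' red-noise significance ([significance()]) and ridge extraction
#' ([extractRidges()]).
#'
#' @param us a [UniformSeries-class] (use [regularize()] first for
#'   irregular data).
#' @param periodMin,periodMax period band of interest, seconds (defaults
#'   16 and 128).
#' @param alpha significance level (default 0.05).
#' @param fixOutliers run [removeOutliers()] first (default TRUE).
#' @param madK MAD multiplier for outlier flagging.
#' @param minPowerFrac,maxPerTime ridge extraction settings.
#' @param dj,omega0 transform settings, see [cwt()].
#' @return list: \code{series} (filtered), \code{trend}, \code{spectrum}
#'   (significance-tested [CwtSpectrum-class]), \code{ridges}
#'   ([RidgeSet-class]), \code{detection} (proportion of trustworthy time
#'   with a ridge), \code{outliers} (report, or NULL).
#' @export
analyzeOscillations <- function(us, periodMin = 16, periodMax = 128,
                                alpha = 0.05, fixOutliers = TRUE,
                                madK = 5, minPowerFrac = 0.05,
                                maxPerTime = 2, dj = 1 / 12, omega0 = 6) {
  stopifnot(is(us, "UniformSeries"))
  outliers <- NULL
  if (fixOutliers) {
    fixed <- removeOutliers(us, madK = madK)
    us <- fixed$series
    outliers <- fixed$report
  }
  bf <- bandFilter(us, periodMin, periodMax)
  spec <- significance(cwt(bf$filtered, dj = dj, omega0 = omega0,
                           null = us),
                       alpha = alpha)
  ridges <- extractRidges(spec, minPowerFrac = minPowerFrac,
                          maxPerTime = maxPerTime)
  list(series = bf$filtered, trend = bf$trend, spectrum = spec,
       ridges = ridges, detection = detectionProportion(ridges),
       outliers = outliers)
}

#' Standard synthetic kymograph set for method comparison
#'
#' The conditions used when comparing tip-detection methods (noise and
#' detection-proportion orderings): a long, moderately noisy, low-amplitude
#' oscillatory kymograph where detectability genuinely differs between
#' methods — SNR (plateau-background)/noise of 5 and a 0.12 um position
#' oscillation at period 48 s over steady 2 um/min growth.
#'
#' @param nFrames number of frames (default 400).
#' @param seed RNG seed.
#' @return as [simulateKymograph()].
#' @export
standardComparisonKymograph <- function(nFrames = 400, seed = 1) {
  simulateKymograph(nFrames = nFrames, nPx = 60 + ceiling(nFrames * 0.75),
                    x0 = 40, amp = 0.12, noiseSd = 18, seed = seed)
}
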