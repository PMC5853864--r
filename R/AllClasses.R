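#' @import methods
NULL

#' Kymograph: a time-by-space fluorescence matrix with calibration
#'
#' Rows are frames (time), columns are pixels along the scan line through the
#' cell midline. After orientation normalization the cell occupies the
#' low-index columns and the background the high-index columns.
#'
#' @slot values numeric matrix, frames x pixels, arbitrary intensity units.
#' @slot dt frame interval in seconds.
#' @slot dx pixel size in micrometres.
#' @slot channel channel label, e.g. \code{"YFP"}, \code{"CFP"}, \code{"ratio"}.
#' @slot flipped \code{TRUE} if the column order was reversed on import to put
#'   the cell at low indices.
#'
#' @exportClass Kymograph
setClass("Kymograph",
  representation(values = "matrix", dt = "numeric", dx = "numeric",
                 channel = "character", flipped = "logical"),
  prototype(channel = "raw", flipped = FALSE))

setValidity("Kymograph", function(object) {
  v <- object@values
  if (!is.numeric(v) || length(dim(v)) != 2L)
    return("'values' must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 2L)
    return("'values' must have at least 1 frame and 2 pixels")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    return("'dt' must be a single positive number (seconds)")
  if (length(object@dx) != 1L || !is.finite(object@dx) || object@dx <= 0)
    return("'dx' must be a single positive number (micrometres)")
  TRUE
})

#' RawSeries: an irregularly sampled time series
#'
#' @slot t sample times in seconds, strictly increasing.
#' @slot v values; units recorded in \code{units}.
#' @slot units unit label (e.g. \code{"um/min"}, \code{"pmol/cm2/s"}, \code{"ratio"}).
#'
#' @exportClass RawSeries
setClass("RawSeries",
  representation(t = "numeric", v = "numeric", units = "character"),
  prototype(units = ""))

setValidity("RawSeries", function(object) {
  if (length(object@t) != length(object@v))
    return("'t' and 'v' must have equal length")
  tt <- object@t[!is.na(object@t)]
  if (any(diff(tt) <= 0))
    return("'t' must be strictly increasing")
  TRUE
})

#' UniformSeries: a regularly sampled time series
#'
#' Implied sample times are \code{t0 + (0:(n-1)) * dt}.
#'
#' @slot t0 time of the first sample, seconds.
#' @slot dt sampling interval, seconds.
#' @slot v values (no missing values after preparation).
#' @slot units unit label.
#'
#' @exportClass UniformSeries
setClass("UniformSeries",
  representation(t0 = "numeric", dt = "numeric", v = "numeric",
                 units = "character"),
  prototype(t0 = 0, units = ""))

setValidity("UniformSeries", function(object) {
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    return("'dt' must be a single positive number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    return("'t0' must be a single finite number")
  if (length(object@v) < 1L) return("'v' must be non-empty")
  TRUE
})

#' TipTrace: per-frame tip position estimates
#'
#' Positions are on the pixel grid of the source kymograph, 0-based, pixel
#' centres at integer coordinates; the regression method yields real-valued
#' (subpixel) positions, the threshold method integers. \code{NA} marks frames
#' where detection failed.
#'
#' @slot t frame times, seconds.
#' @slot posPx tip position per frame, pixels.
#' @slot dx pixel size, micrometres (so \code{posUm(x) = posPx * dx}).
#' @slot method one of \code{"threshold"}, \code{"regression"}, \code{"external"}.
#' @slot smoothed whether [smoothTrace()] has been applied.
#'
#' @exportClass TipTrace
setClass("TipTrace",
  representation(t = "numeric", posPx = "numeric", dx = "numeric",
                 method = "character", smoothed = "logical"),
  prototype(method = "regression", smoothed = FALSE, dx = 1))

setValidity("TipTrace", function(object) {
  if (length(object@t) != length(object@posPx))
    return("'t' and 'posPx' must have equal length")
  if (!object@method %in% c("threshold", "regression", "external"))
    return("'method' must be threshold, regression or external")
  TRUE
})

#' AlignedKymograph: kymograph resampled to distance-from-tip coordinates
#'
#' Column k holds, for every frame, the intensity at distance
#' \code{distUm[k]} from the tip estimate, increasing from the tip (0) into
#' the cell (shank). Bins beyond a frame's extent are \code{NA}.
#'
#' @slot values numeric matrix, frames x distance bins.
#' @slot distUm distance from tip per column, micrometres.
#' @slot dt frame interval, seconds.
#'
#' @exportClass AlignedKymograph
setClass("AlignedKymograph",
  representation(values = "matrix", distUm = "numeric", dt = "numeric"))

setValidity("AlignedKymograph", function(object) {
  if (ncol(object@values) != length(object@distUm))
    return("'distUm' length must match number of columns")
  if (any(diff(object@distUm) <= 0))
    return("'distUm' must be strictly increasing")
  TRUE
})

#' BackgroundEstimate: background intensity distribution and quantile cutoff
#'
#' @slot samples background pixel intensities pooled across frames.
#' @slot cutoff intensity at the chosen quantile of \code{samples}.
#' @slot quantile the quantile used (default 0.99).
#'
#' @exportClass BackgroundEstimate
setClass("BackgroundEstimate",
  representation(samples = "numeric", cutoff = "numeric", quantile = "numeric"))

setValidity("BackgroundEstimate", function(object) {
  if (object@quantile <= 0 || object@quantile > 1)
    return("'quantile' must be in (0, 1]")
  expected <- stats::quantile(object@samples, object@quantile, names = FALSE,
                              na.rm = TRUE)
  if (!isTRUE(all.equal(expected, object@cutoff, tolerance = 1e-8)))
    return("'cutoff' must equal the empirical quantile of 'samples'")
  TRUE
})

#' MraDecomposition: additive multiresolution analysis of a uniform series
#'
#' Detail level j nominally carries periods in (2^j dt, 2^(j+1) dt] seconds;
#' the smooth carries the remaining trend. Details plus smooth sum to the
#' input exactly (to numerical precision).
#'
#' @slot details list of numeric vectors D_1 ... D_J (finest first).
#' @slot smooth numeric vector S_J, the trend.
#' @slot dt sampling interval, seconds.
#' @slot filter wavelet filter name (\code{"la8"}, \code{"d4"} or \code{"haar"}).
#'
#' @exportClass MraDecomposition
setClass("MraDecomposition",
  representation(details = "list", smooth = "numeric", dt = "numeric",
                 filter = "character"))

setValidity("MraDecomposition", function(object) {
  n <- length(object@smooth)
  if (!all(vapply(object@details, length, 1L) == n))
    return("all detail levels must have the length of 'smooth'")
  TRUE
})

#' CwtSpectrum: continuous Morlet wavelet power over (period, time)
#'
#' @slot power |W|^2, periods x times.
#' @slot wave complex wavelet coefficients (kept for cross-wavelet analysis).
#' @slot periods Fourier-equivalent periods per scale, seconds (log-spaced).
#' @slot scales wavelet scales, seconds.
#' @slot times sample times, seconds.
#' @slot coi per-time maximum trustworthy period, seconds.
#' @slot signif logical matrix, TRUE where power exceeds the red-noise
#'   threshold at level alpha; empty until [significance()] is applied.
#' @slot ar1 lag-1 autocorrelation estimated from the input.
#' @slot alpha significance level used (NA before testing).
#' @slot sigma2 input variance (red-noise spectrum normalization).
#' @slot omega0 Morlet nondimensional frequency.
#'
#' @exportClass CwtSpectrum
setClass("CwtSpectrum",
  representation(power = "matrix", wave = "matrix", periods = "numeric",
                 scales = "numeric", times = "numeric", coi = "numeric",
                 signif = "matrix", ar1 = "numeric", alpha = "numeric",
                 sigma2 = "numeric", omega0 = "numeric"),
  prototype(alpha = NA_real_, signif = matrix(logical(0), 0, 0)))

setValidity("CwtSpectrum", function(object) {
  if (nrow(object@power) != length(object@periods) ||
      ncol(object@power) != length(object@times))
    return("'power' must be periods x times")
  if (any(object@power < 0, na.rm = TRUE)) return("'power' must be >= 0")
  if (length(object@coi) != length(object@times))
    return("'coi' must have one entry per time")
  TRUE
})

#' CrossSpectrum: cross-wavelet transform of two series
#'
#' \code{phase} is the phase difference phi_x - phi_y in (-pi, pi]: positive
#' at period P means the first series leads (occurs before) the second by
#' \code{phase/(2*pi) * P} seconds.
#'
#' @slot xpower |W_xy|, periods x times.
#' @slot phase phase difference, radians, periods x times.
#' @slot wave complex cross-wavelet coefficients W_x * Conj(W_y).
#' @slot periods,scales,times,coi,signif,alpha as in [CwtSpectrum-class].
#' @slot ar1 estimated lag-1 autocorrelations of the two inputs.
#' @slot sigma2 variances of the two inputs.
#'
#' @exportClass CrossSpectrum
setClass("CrossSpectrum",
  representation(xpower = "matrix", phase = "matrix", wave = "matrix",
                 periods = "numeric", scales = "numeric", times = "numeric",
                 coi = "numeric", signif = "matrix", ar1 = "numeric",
                 alpha = "numeric", sigma2 = "numeric"),
  prototype(alpha = NA_real_, signif = matrix(logical(0), 0, 0)))

setValidity("CrossSpectrum", function(object) {
  if (nrow(object@xpower) != length(object@periods) ||
      ncol(object@xpower) != length(object@times))
    return("'xpower' must be periods x times")
  if (any(abs(object@phase) > pi + 1e-12, na.rm = TRUE))
    return("'phase' must lie in (-pi, pi]")
  TRUE
})

#' RidgeSet: per-time power maxima of a (cross-)wavelet spectrum
#'
#' @slot points data.frame with columns \code{time_s}, \code{period_s},
#'   \code{power}, \code{amplitude} (and \code{phase} for cross-spectra);
#'   every point is significant and outside the cone of influence.
#' @slot maxPerTime maximum number of ridges kept per time point.
#' @slot times the spectrum's full time grid (for detection bookkeeping).
#' @slot coiTimes logical, which time grid points lie in the trustworthy
#'   region (some period below the cone of influence).
#'
#' @exportClass RidgeSet
setClass("RidgeSet",
  representation(points = "data.frame", maxPerTime = "numeric",
                 times = "numeric", coiTimes = "logical"))

setValidity("RidgeSet", function(object) {
  need <- c("time_s", "period_s", "power", "amplitude")
  if (!all(need %in% names(object@points)))
    return("'points' must have columns time_s, period_s, power, amplitude")
  TRUE
})

#' MixtureFit: two-component univariate Gaussian mixture fit
#'
#' @slot means,sds,weights component parameters, length 2; weights sum to 1.
#' @slot main index (1 or 2) of the main component (larger weight; ties
#'   broken by smaller sd).
#' @slot loglik maximized log-likelihood.
#' @slot seed RNG seed used for the multi-start initialization.
#'
#' @exportClass MixtureFit
setClass("MixtureFit",
  representation(means = "numeric", sds = "numeric", weights = "numeric",
                 main = "integer", loglik = "numeric", seed = "integer"))

setValidity("MixtureFit", function(object) {
  if (length(object@means) != 2L || length(object@sds) != 2L ||
      length(object@weights) != 2L)
    return("two components required")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (any(object@sds <= 0)) return("sds must be positive")
  TRUE
})
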