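#' Cross-wavelet synchronization analysis
#'
#' Joint periodicity, phase relationship and time-resolved delay between
#' two concurrently measured series. The phase difference is
#' \code{Delta phi = phi_x - phi_y}: positive phase at period P means the
#' first series leads (occurs before) the second, by
#' \code{delay = Delta phi / (2 pi) * P} seconds.
#'
#' @name sync-module
NULL

#' Match two raw series onto a common filtered grid
#'
#' Both series are regularized ([regularize()]) onto the identical time
#' grid covering their overlap, then band-filtered ([bandFilter()]) with a
#' shared period band (trend and noise removed).
#'
#' @param a,b [RawSeries-class] with overlapping time ranges.
#' @param dtTarget common sampling interval, seconds (default: median
#'   observed step of the first series).
#' @param periodMin,periodMax shared period band, seconds (defaults 16 and
#'   128).
#' @param span loess span for regularization.
#' @return list of two matched, filtered [UniformSeries-class] (\code{a},
#'   \code{b}), their extracted trends (\code{trendA}, \code{trendB}) and
#'   the unfiltered regularized series (\code{prepA}, \code{prepB}) for
#'   red-noise null estimation.
#' @export
matchSeries <- function(a, b, dtTarget = NULL, periodMin = 16,
                        periodMax = 128, span = NULL) {
  lo <- max(min(a@t), min(b@t))
  hi <- min(max(a@t), max(b@t))
  if (hi <= lo) stop("series do not overlap in time")
  if (is.null(dtTarget)) dtTarget <- stats::median(diff(a@t))
  grid_n <- floor((hi - lo) / dtTarget) + 1
  if (grid_n < 32) stop("overlap shorter than 32 samples")
  grid <- seq(lo, hi, by = dtTarget)
  onGrid <- function(rs) {
    keep <- rs@t >= lo - 2 * dtTarget & rs@t <= hi + 2 * dtTarget
    t <- rs@t[keep]; v <- rs@v[keep]
    if (is.null(span)) span <- 7 / length(t)
    fit <- stats::loess(v ~ t, span = span, degree = 2,
                        control = stats::loess.control(surface = "direct"))
    UniformSeries(as.numeric(stats::predict(fit, newdata = grid)),
                  dt = dtTarget, t0 = lo, units = rs@units)
  }
  ua <- onGrid(a)
  ub <- onGrid(b)
  fa <- bandFilter(ua, periodMin, periodMax)
  fb <- bandFilter(ub, periodMin, periodMax)
  list(a = fa$filtered, b = fb$filtered,
       trendA = fa$trend, trendB = fb$trend,
       prepA = ua, prepB = ub)
}

#' Cross-wavelet transform of two matched series
#'
#' \code{W_xy = W_a * Conj(W_b)} on shared scales; cross power is
#' \code{|W_xy|} and phase is \code{Arg(W_xy)}. Significance is assessed
#' against the product of the two red-noise spectra.
#'
#' @param a,b [UniformSeries-class] on the same time grid.
#' @param nullA,nullB optional pre-filter series for red-noise null
#'   estimation, see [cwt()] (pass \code{prepA}/\code{prepB} from
#'   [matchSeries()]).
#' @inheritParams cwt
#' @return a [CrossSpectrum-class].
#' @export
xwt <- function(a, b, dj = 1 / 12, s0 = NULL, J = NULL, omega0 = 6,
                nullA = NULL, nullB = NULL) {
  if (length(a@v) != length(b@v) || abs(a@dt - b@dt) > 1e-9 ||
      abs(a@t0 - b@t0) > 1e-9)
    stop("series must share the same time grid")
  wa <- cwt(a, dj = dj, s0 = s0, J = J, omega0 = omega0, null = nullA)
  wb <- cwt(b, dj = dj, s0 = s0, J = J, omega0 = omega0, null = nullB)
  wave <- wa@wave * Conj(wb@wave)
  new("CrossSpectrum", xpower = abs(wave), phase = Arg(wave), wave = wave,
      periods = wa@periods, scales = wa@scales, times = wa@times,
      coi = pmin(wa@coi, wb@coi), ar1 = c(wa@ar1, wb@ar1),
      sigma2 = c(wa@sigma2, wb@sigma2))
}

# quantile of Z = |W_x W_y*| * nu / (sigma_x sigma_y sqrt(Px Py)) for two
# independent chi_2-distributed spectra: P(Z > z) = z K_1(z)
.cross_quantile <- function(alpha) {
  stats::uniroot(function(z) z * besselK(z, 1) - alpha,
                 lower = 1e-8, upper = 50, tol = 1e-10)$root
}

#' @describeIn significance cross-wavelet test: \code{|W_xy|} against the
#'   geometric mean of the two variance-matched red-noise spectra.
#' @export
setMethod("significance", "CrossSpectrum", function(spec, alpha = 0.05) {
  dt <- diff(spec@times[1:2])
  f <- dt / spec@periods
  pkx <- .rednoise_spectrum(spec@ar1[1], f)
  pky <- .rednoise_spectrum(spec@ar1[2], f)
  z <- if (alpha >= 1) 0 else .cross_quantile(alpha)
  level <- sqrt(prod(spec@sigma2)) * sqrt(pkx * pky) * z / 2
  spec@signif <- sweep(spec@xpower, 1, level, `>`)
  spec@alpha <- alpha
  spec
})

#' Time-resolved delay from cross-wavelet phase
#'
#' For each joint ridge point, \code{delay = phase / (2 pi) * period},
#' which lies in \code{(-period/2, period/2]}. Positive delay: the first
#' series leads (occurs before) the second. Relative amplitude is cross
#' power normalized by its maximum over the ridge set.
#'
#' @param xs a [CrossSpectrum-class] (for provenance; phases are read from
#'   the ridge table).
#' @param ridges a [RidgeSet-class] extracted from \code{xs}.
#' @return data.frame: \code{time_s}, \code{delay_s}, \code{period_s},
#'   \code{phase}, \code{relamp}.
#' @export
phaseToDelay <- function(xs, ridges) {
  pts <- ridges@points
  if (nrow(pts) == 0L)
    return(data.frame(time_s = numeric(0), delay_s = numeric(0),
                      period_s = numeric(0), phase = numeric(0),
                      relamp = numeric(0)))
  if (is.null(pts$phase)) stop("ridges must come from a cross spectrum")
  delay <- pts$phase / (2 * pi) * pts$period_s
  data.frame(time_s = pts$time_s, delay_s = delay,
             period_s = pts$period_s, phase = pts$phase,
             relamp = pts$power / max(pts$power))
}

#' Circular summary of cross-wavelet phases
#'
#' Binned phase histogram on the circle with circular mean and resultant
#' length R (1 = perfectly concentrated, 0 = uniform).
#'
#' @param xs a [CrossSpectrum-class].
#' @param ridges a [RidgeSet-class] with at least 10 points.
#' @param nBins number of histogram bins (default 16).
#' @return list: \code{breaks}, \code{counts}, \code{mean} (radians),
#'   \code{R}, \code{n}.
#' @export
phaseHistogram <- function(xs, ridges, nBins = 16) {
  phases <- ridges@points$phase
  if (is.null(phases) || length(phases) < 10L)
    stop("need at least 10 ridge points with phases")
  breaks <- seq(-pi, pi, length.out = nBins + 1)
  counts <- table(cut(phases, breaks, include.lowest = TRUE))
  z <- mean(exp(1i * phases))
  list(breaks = breaks, counts = as.integer(counts),
       mean = Arg(z), R = Mod(z), n = length(phases))
}

#' Flag synchronized windows
#'
#' A window is synchronized when the circular SD of its ridge phases is
#' below \code{tol} and joint significance (a joint ridge — a significant
#' cross-power peak outside the cone of influence) holds for more than
#' 80\% of its time points.
#'
#' @param xs a significance-tested [CrossSpectrum-class].
#' @param ridges a [RidgeSet-class] from \code{xs}.
#' @param window window length, seconds.
#' @param tol circular-SD threshold, radians (default 0.5).
#' @return data.frame: \code{start_s}, \code{end_s}, \code{synchronized},
#'   \code{circSD}, \code{fracSignif}.
#' @export
synchronyFlag <- function(xs, ridges, window, tol = 0.5) {
  if (is.na(xs@alpha)) stop("run significance() first")
  times <- xs@times
  sigCol <- times %in% ridges@points$time_s
  edges <- seq(min(times), max(times), by = window)
  if (edges[length(edges)] < max(times)) {
    # merge a short remainder into the last window rather than judging a stub
    if (max(times) - edges[length(edges)] < window / 2) {
      edges[length(edges)] <- max(times)
    } else {
      edges <- c(edges, max(times))
    }
  }
  pts <- ridges@points
  out <- lapply(seq_len(length(edges) - 1), function(i) {
    lo <- edges[i]; hi <- edges[i + 1]
    inWin <- times >= lo & times <= hi & ridges@coiTimes
    ph <- pts$phase[pts$time_s >= lo & pts$time_s <= hi]
    circSD <- if (length(ph) >= 3) {
      R <- Mod(mean(exp(1i * ph)))
      sqrt(-2 * log(max(R, 1e-12)))
    } else Inf
    fracSig <- if (any(inWin)) mean(sigCol[inWin]) else 0
    data.frame(start_s = lo, end_s = hi,
               synchronized = circSD < tol && fracSig > 0.8,
               circSD = circSD, fracSignif = fracSig)
  })
  do.call(rbind, out)
}
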