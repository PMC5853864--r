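#' Pre-filtering: regular sampling and outlier handling
#'
#' Most downstream analyses require a homogeneous sampling rate, while
#' experimental series (e.g. ion-selective vibrating probe exports) have
#' variable time steps and occasional gross outliers. This module
#' interpolates onto a regular grid by local polynomial regression (loess)
#' and detects/restores additive outliers.
#'
#' @name tsprep
NULL

#' Resample a series onto a regular time grid
#'
#' Local quadratic regression (loess, tricube weights) of value on time,
#' evaluated on the grid \code{seq(min(t), max(t), dtTarget)}. Polynomials
#' up to degree 2 are reproduced exactly; missing values are excluded
#' before fitting.
#'
#' @param rs a [RawSeries-class] with at least 10 samples.
#' @param dtTarget target interval, seconds (default: the median observed
#'   time step).
#' @param span loess span as a fraction of the series (default: 7 points'
#'   worth, \code{7 / n} — local enough that on-grid samples are closely
#'   reproduced; must leave each local fit determined).
#' @return a [UniformSeries-class].
#' @export
regularize <- function(rs, dtTarget = NULL, span = NULL) {
  stopifnot(is(rs, "RawSeries"))
  t <- rs@t; v <- rs@v
  ok <- is.finite(t) & is.finite(v)
  t <- t[ok]; v <- v[ok]
  n <- length(t)
  if (n < 10L) stop("need at least 10 samples")
  if (is.null(dtTarget)) dtTarget <- stats::median(diff(t))
  if (dtTarget <= 0) stop("'dtTarget' must be positive")
  if (is.null(span)) span <- 7 / n
  if (span * n < 4) stop("'span' under-determines the local fit")
  grid <- seq(min(t), max(t), by = dtTarget)
  fit <- stats::loess(v ~ t, span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  UniformSeries(as.numeric(stats::predict(fit, newdata = grid)),
                dt = dtTarget, t0 = grid[1], units = rs@units)
}

#' Detect and restore outliers in a uniform series
#'
#' \code{method = "mad"} (default): points whose residual from a running
#' median exceeds \code{madK} times the median absolute deviation of the
#' residuals are flagged as additive outliers and replaced by a local
#' regression prediction from the clean points. \code{method = "model"}
#' additionally scans the standardized innovations of a low-order
#' autoregressive fit and classifies flagged points as additive outliers
#' (replaced) or level shifts (reported but left untouched — a persistent
#' shift may be biology, not artefact).
#'
#' @param us a [UniformSeries-class] with \code{n >= 20}.
#' @param madK MAD multiplier (default 5).
#' @param method \code{"mad"} or \code{"model"}.
#' @param window running-median window, samples (odd; default 11).
#' @param replaceSpan loess span for the replacement fit (default
#'   \code{max(15 / n, 0.05)}).
#' @return list with \code{series} (corrected [UniformSeries-class]) and
#'   \code{report} (data.frame: index, type, original, replaced). Missing
#'   values in the input are treated as outliers of type \code{"NA"} and
#'   filled the same way.
#' @export
removeOutliers <- function(us, madK = 5, method = c("mad", "model"),
                           window = 11, replaceSpan = NULL) {
  method <- match.arg(method)
  v <- us@v
  n <- length(v)
  if (n < 20L) stop("need at least 20 samples")
  naIdx <- which(!is.finite(v))
  if (length(naIdx) > 0L) {
    if (length(naIdx) > n / 2) stop("more than half the values are missing")
    fin <- which(is.finite(v))
    v[naIdx] <- stats::approx(fin, v[fin], xout = naIdx, rule = 2)$y
  }
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  med <- stats::runmed(v, window, endrule = "median")
  resid <- v - med
  madv <- stats::mad(resid)
  flagged <- if (madv > 0) abs(resid) > madK * madv else abs(resid) > 0
  type <- rep("AO", n)
  if (method == "model") {
    arfit <- tryCatch(stats::ar(v, order.max = 2, aic = TRUE),
                      error = function(e) NULL)
    cand <- which(flagged)
    if (!is.null(arfit) && length(arfit$resid) == n) {
      z <- arfit$resid / sqrt(arfit$var.pred)
      cand <- sort(union(cand, which(!is.na(z) & abs(z) > madK)))
    }
    scale <- madK * max(madv, 1e-12)
    for (i in cand) {
      # a level shift moves the local median permanently; an additive
      # outlier leaves the medians on both sides in agreement
      before <- v[max(1, i - 6):max(1, i - 1)]
      after <- v[min(i, n):min(i + 5, n)]
      if (length(before) >= 3 && length(after) >= 3 &&
          abs(stats::median(after) - stats::median(before)) > scale) {
        flagged[i] <- TRUE
        type[i] <- "LS"
      } else {
        flagged[i] <- TRUE
      }
    }
  }
  flagged[naIdx] <- TRUE
  type[naIdx] <- "NA"
  if (sum(!flagged) < max(10L, ceiling(0.05 * n)))
    stop("nearly all points flagged: 'madK' too small for this series")
  idx <- which(flagged)
  out <- v
  replaced <- rep(NA_real_, length(idx))
  replaceIdx <- idx[type[idx] %in% c("AO", "NA")]  # level shifts stay
  if (length(replaceIdx) > 0L) {
    clean <- which(!flagged)
    if (is.null(replaceSpan)) replaceSpan <- max(15 / n, 0.05)
    tt <- sampleTimes(us)
    fit <- stats::loess(v[clean] ~ tt[clean], span = replaceSpan, degree = 2,
                        control = stats::loess.control(surface = "direct"))
    out[replaceIdx] <- as.numeric(stats::predict(fit,
                                                 newdata = tt[replaceIdx]))
    replaced[match(replaceIdx, idx)] <- out[replaceIdx]
  }
  orig <- us@v
  list(series = UniformSeries(out, dt = us@dt, t0 = us@t0, units = us@units),
       report = data.frame(index = idx, type = type[idx],
                           original = orig[idx], replaced = replaced))
}
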