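#' Tip detection on kymograph frames
#'
#' Two estimators of the advancing cell edge ("tip") on an
#' orientation-normalized fluorescence profile (cell at low pixel indices,
#' background at high indices). Positions are 0-based with pixel centres at
#' integer coordinates.
#'
#' @name tipdetect
NULL

#' Threshold tip detection (whole-pixel comparison method)
#'
#' Scanning from the background toward the cell, the boundary pixel is the
#' largest index p with \code{profile[p] >= threshold} and all pixels beyond
#' it below threshold — i.e. the pixel where the threshold is last exceeded.
#' Resolution is limited to whole pixels.
#'
#' @param profile numeric vector, fluorescence per pixel.
#' @param threshold intensity threshold.
#' @return 0-based pixel index, or \code{NA} if no pixel reaches the
#'   threshold.
#' @export
detectTipThreshold <- function(profile, threshold) {
  idx <- which(profile >= threshold)
  if (length(idx) == 0L) return(NA_real_)
  as.numeric(max(idx) - 1L)
}

.moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- (w - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Subpixel tip detection by regression on the edge slope
#'
#' The edge is first localized on a more heavily smoothed copy of the
#' profile (the last half-height crossing between the profile maximum and
#' the background side — the argmin of a raw difference series is unstable
#' under noise). The pixel of steepest descent is then taken within one
#' pixel of that crossing, an ordinary least-squares line is fitted to the
#' lightly smoothed intensities (moving average of \code{presmoothWindow}
#' pixels) within \code{fitHalfwidth} pixels of it, and the tip position is
#' the real-valued coordinate where the line crosses \code{refLevel}. For a
#' linear edge the estimator recovers the line exactly; it is
#' translation-equivariant for interior tips.
#'
#' @param profile numeric vector, fluorescence per pixel
#'   (orientation-normalized: cell at low indices).
#' @param presmoothWindow moving-average window for the fitted profile, px
#'   (default 3; 1 disables).
#' @param fitHalfwidth half-width of the fit window, px (default 2, i.e. a
#'   5-pixel fit).
#' @param refLevel intensity level whose crossing defines the tip.
#'   \code{NULL} (default): the half-height level, the midpoint of the
#'   frame's plateau and background estimates — crossing there has no lever
#'   arm, minimizing noise amplification, and is unbiased at the centre of
#'   a sigmoidal edge. \code{"background"}: the frame's background
#'   estimate (for a noiseless logistic edge of scale w the tangent at the
#'   steepest slope crosses background at centre + 2w). A number: used as
#'   given (0 after background subtraction).
#' @param locWindow moving-average window for edge localization, px
#'   (default 9).
#' @return subpixel tip position (0-based pixels), or \code{NA} when no
#'   descending edge is found.
#' @export
detectTipRegression <- function(profile, presmoothWindow = 3,
                                fitHalfwidth = 2, refLevel = NULL,
                                locWindow = 9) {
  n <- length(profile)
  if (n < 2L * fitHalfwidth + 1L)
    stop("profile shorter than the fit window")
  s <- .moving_average(profile, presmoothWindow)
  h <- .moving_average(profile, max(presmoothWindow, locWindow))
  # localization: last half-height crossing of the heavy-smoothed profile
  k <- max(3L, floor(0.25 * n))
  bg0 <- stats::median(h[(n - k + 1L):n])
  level <- (max(h) + bg0) / 2
  above <- which(h >= level)
  if (length(above) == 0L || max(above) >= n) return(NA_real_)
  centre <- max(above)
  # per-frame plateau / background estimates from the raw profile
  plat <- stats::median(profile[seq_len(max(1L, centre - 5L))])
  bg <- if (centre + 6L <= n) stats::median(profile[(centre + 6L):n]) else bg0
  if (is.null(refLevel)) {
    refLevel <- (plat + bg) / 2
  } else if (identical(refLevel, "background")) {
    refLevel <- bg
  }
  # steepest descent of the fitted profile, within a pixel of the crossing
  slo <- max(1L, centre - 1L)
  shi <- min(n - 1L, centre + 1L)
  d <- s[(slo + 1L):(shi + 1L)] - s[slo:shi]
  steep <- which(d == min(d))
  steep <- steep[length(steep)]              # tie-break: most distal
  st <- slo + steep - 1L                     # left pixel of steepest drop
  lo <- max(1L, st - fitHalfwidth)
  hi <- min(n, st + fitHalfwidth)
  px <- (lo:hi) - 1L                         # 0-based coordinates
  fit <- stats::lm.fit(cbind(1, px), s[lo:hi])
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (!is.finite(b) || b >= 0) return(NA_real_)
  as.numeric((refLevel - a) / b)
}

#' Trace the tip across all frames of a kymograph
#'
#' Applies [detectTipThreshold()] or [detectTipRegression()] to every frame.
#' For the threshold method the default threshold is the midpoint between
#' the 10th and 99th intensity percentiles of each frame.
#'
#' @param kymo a [Kymograph-class] (orientation-normalized).
#' @param method \code{"regression"} (subpixel, featured) or
#'   \code{"threshold"}.
#' @param threshold intensity threshold for the threshold method
#'   (default \code{NULL}: per-frame percentile midpoint).
#' @param presmoothWindow,fitHalfwidth,refLevel,locWindow passed to
#'   [detectTipRegression()].
#' @return a [TipTrace-class].
#' @export
traceTip <- function(kymo, method = c("regression", "threshold"),
                     threshold = NULL, presmoothWindow = 3,
                     fitHalfwidth = 2, refLevel = NULL, locWindow = 9) {
  method <- match.arg(method)
  v <- kymo@values
  pos <- vapply(seq_len(nrow(v)), function(f) {
    prof <- v[f, ]
    if (method == "threshold") {
      th <- threshold
      if (is.null(th)) {
        q <- stats::quantile(prof, c(0.10, 0.99), names = FALSE)
        th <- mean(q)
      }
      detectTipThreshold(prof, th)
    } else {
      detectTipRegression(prof, presmoothWindow, fitHalfwidth, refLevel,
                          locWindow)
    }
  }, numeric(1))
  new("TipTrace", t = (seq_len(nrow(v)) - 1) * kymo@dt, posPx = pos,
      dx = kymo@dx, method = method, smoothed = FALSE)
}

#' Smooth a tip trace with a local polynomial fit
#'
#' Local quadratic regression (loess) of position on time, evaluated at the
#' original frame times; missing frames are filled by the fit. Assumes no
#' sudden jumps of the tip; larger spans suppress more of the
#' high-frequency oscillation, so only a small portion of the series should
#' be used.
#'
#' @param trace a [TipTrace-class] with at least 10 non-missing points.
#' @param span fraction of the series used per local fit. Default
#'   \code{NULL}: 20 points' worth (\code{20 / length(trace)}), capped at 1.
#' @return the smoothed [TipTrace-class] (no missing values).
#' @export
smoothTrace <- function(trace, span = NULL) {
  ok <- !is.na(trace@posPx)
  if (sum(ok) < 10L) stop("need at least 10 non-missing points")
  if (is.null(span)) span <- min(1, 20 / length(trace@posPx))
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  if (span * sum(ok) < 4) stop("'span' under-determines the local fit")
  fit <- stats::loess(trace@posPx[ok] ~ trace@t[ok], span = span, degree = 2,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct"))
  sm <- stats::predict(fit, newdata = trace@t)
  new("TipTrace", t = trace@t, posPx = as.numeric(sm), dx = trace@dx,
      method = trace@method, smoothed = TRUE)
}

#' Growth-rate series from a tip trace
#'
#' First differences of position, converted to micrometres per minute and
#' timestamped at interval midpoints:
#' \code{rate_i = (pos[i+1] - pos[i]) * dx / dt * 60}.
#'
#' @param trace a [TipTrace-class] with uniform frame times.
#' @param dx pixel size, um (default: the trace's own).
#' @param dt frame interval, s (default: inferred from the trace times).
#' @return a [UniformSeries-class] in um/min, first sample at the midpoint
#'   of the first frame interval.
#' @export
growthRate <- function(trace, dx = NULL, dt = NULL) {
  if (is.null(dx)) dx <- trace@dx
  if (is.null(dt)) {
    steps <- diff(trace@t)
    if (length(steps) == 0L) stop("trace too short")
    if (max(abs(steps - steps[1])) > 1e-8 * steps[1])
      stop("trace must be uniform in time")
    dt <- steps[1]
  }
  rate <- diff(trace@posPx) * dx / dt * 60
  UniformSeries(rate, dt = dt, t0 = trace@t[1] + dt / 2, units = "um/min")
}
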