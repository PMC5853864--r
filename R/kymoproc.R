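#' Ratiometric and single-channel kymograph processing
#'
#' Background estimation from the region beyond the tip, channel-specific
#' background subtraction and ratio computation, tip alignment, and
#' extraction of fluorescence series at fixed distances from the tip.
#'
#' @name kymoproc
NULL

#' Estimate the background intensity distribution beyond the tip
#'
#' Pools, over all frames with a tip estimate, the pixels strictly beyond
#' \code{tip + marginPx}; the cutoff is an arbitrary quantile in the tail
#' of this distribution (default 99\%), which separates background from
#' signal when the two distributions are well separated.
#'
#' @param kymo a [Kymograph-class].
#' @param trace the [TipTrace-class] for this kymograph (frames with
#'   \code{NA} positions are excluded).
#' @param marginPx pixels beyond the tip excluded as blurred edge
#'   (default 3).
#' @param quantile quantile for the cutoff (default 0.99).
#' @return a [BackgroundEstimate-class].
#' @export
estimateBackground <- function(kymo, trace, marginPx = 3, quantile = 0.99) {
  v <- kymo@values
  stopifnot(length(trace@posPx) == nrow(v))
  samples <- vector("list", nrow(v))
  for (f in seq_len(nrow(v))) {
    tip <- trace@posPx[f]
    if (is.na(tip)) next
    from <- floor(tip + marginPx) + 1L  # first 0-based index > tip + margin
    if (from + 1L <= ncol(v)) samples[[f]] <- v[f, (from + 1L):ncol(v)]
  }
  samples <- unlist(samples)
  if (length(samples) == 0L)
    stop("empty background region: tip + margin beyond the field in all frames")
  cutoff <- stats::quantile(samples, quantile, names = FALSE)
  new("BackgroundEstimate", samples = as.numeric(samples), cutoff = cutoff,
      quantile = quantile)
}

#' Background-subtracted ratiometric kymograph
#'
#' Computes \code{(YFP - bgY) / (CFP - bgC)} pixelwise; pixels where the
#' denominator does not exceed \code{floor} are masked (\code{NA}) rather
#' than divided.
#'
#' @param yfp,cfp co-registered [Kymograph-class] channels of equal shape
#'   and calibration.
#' @param bgY,bgC background cutoffs per channel (numbers or
#'   [BackgroundEstimate-class]).
#' @param floor minimum denominator intensity (default 1).
#' @return a [Kymograph-class] with channel \code{"ratio"}.
#' @export
ratioKymograph <- function(yfp, cfp, bgY, bgC, floor = 1) {
  if (is(bgY, "BackgroundEstimate")) bgY <- bgY@cutoff
  if (is(bgC, "BackgroundEstimate")) bgC <- bgC@cutoff
  if (!identical(dim(yfp@values), dim(cfp@values)))
    stop("channel shape mismatch")
  if (yfp@dt != cfp@dt || yfp@dx != cfp@dx)
    stop("channel calibration mismatch")
  den <- cfp@values - bgC
  num <- yfp@values - bgY
  ratio <- ifelse(den > floor, num / den, NA_real_)
  Kymograph(ratio, dt = yfp@dt, dx = yfp@dx, channel = "ratio",
            normalize = FALSE)
}

#' Pick the strongest of two channels
#'
#' Tip detection on ratiometric pairs runs on the channel with the higher
#' median intensity.
#'
#' @param a,b [Kymograph-class] channels.
#' @return the stronger channel.
#' @export
strongestChannel <- function(a, b) {
  if (stats::median(a@values) >= stats::median(b@values)) a else b
}

#' Align a kymograph to the tip estimate
#'
#' Each frame is resampled by linear interpolation onto the distance grid
#' \code{d_k = k * dx} measured from that frame's tip estimate, oriented
#' tip (distance 0) to shank (into the cell). Bins beyond a frame's extent
#' are \code{NA}; so is every bin of frames without a tip estimate.
#'
#' @param kymo a [Kymograph-class].
#' @param trace subpixel [TipTrace-class].
#' @return an [AlignedKymograph-class].
#' @export
alignToTip <- function(kymo, trace) {
  v <- kymo@values
  stopifnot(length(trace@posPx) == nrow(v))
  nBins <- ncol(v)
  px <- seq_len(ncol(v)) - 1
  out <- matrix(NA_real_, nrow(v), nBins)
  for (f in seq_len(nrow(v))) {
    tip <- trace@posPx[f]
    if (is.na(tip)) next
    xout <- tip - (seq_len(nBins) - 1)   # pixel coordinate at distance k*dx
    ok <- !is.na(v[f, ])
    if (sum(ok) < 2L) next
    out[f, ] <- stats::approx(px[ok], v[f, ok], xout = xout, rule = 1)$y
  }
  new("AlignedKymograph", values = out,
      distUm = (seq_len(nBins) - 1) * kymo@dx, dt = kymo@dt)
}

#' Extract a fluorescence series at a fixed distance from the tip
#'
#' Per-frame summary (median by default) over the distance bins within
#' \code{centerUm +/- widthUm/2}; e.g. the tip region ~1.1 um wide at
#' ~2.2 um and the shank at ~19.4 um from the tip estimate.
#'
#' @param ak an [AlignedKymograph-class].
#' @param centerUm region centre, um from the tip.
#' @param widthUm region width, um (regions narrower than one pixel give a
#'   single-column series).
#' @param stat \code{"median"} (default) or \code{"mean"}.
#' @param units unit label for the result.
#' @return a [RawSeries-class] (one value per frame; frames with no data in
#'   the region are dropped).
#' @export
extractRegionSeries <- function(ak, centerUm, widthUm = 1.1,
                                stat = c("median", "mean"), units = "") {
  stat <- match.arg(stat)
  cols <- which(ak@distUm >= centerUm - widthUm / 2 &
                ak@distUm <= centerUm + widthUm / 2)
  if (length(cols) == 0L)
    cols <- which.min(abs(ak@distUm - centerUm))
  if (length(cols) == 0L) stop("empty column set for the requested region")
  f <- if (stat == "median") stats::median else mean
  vals <- apply(ak@values[, cols, drop = FALSE], 1, f, na.rm = TRUE)
  t <- (seq_len(nrow(ak@values)) - 1) * ak@dt
  keep <- is.finite(vals)
  RawSeries(t[keep], vals[keep], units = units, collapse = FALSE)
}

#' Normalized tip/shank gradient series
#'
#' \code{(tip - shank) / shank} per frame, on the common time base.
#'
#' @param tip,shank [RawSeries-class] at aligned time points.
#' @return a [RawSeries-class] of the normalized gradient.
#' @export
tipShankGradient <- function(tip, shank) {
  common <- intersect(tip@t, shank@t)
  if (length(common) == 0L) stop("no common time points")
  ti <- tip@v[match(common, tip@t)]
  sh <- shank@v[match(common, shank@t)]
  if (any(sh <= 0)) stop("shank values must be positive")
  RawSeries(common, (ti - sh) / sh, units = "gradient", collapse = FALSE)
}

#' Scan fluorescence series along the tube
#'
#' One region series per centre position from \code{startUm} to
#' \code{stopUm} at \code{stepUm} intervals (e.g. ~1.1 um wide regions at
#' ~1.5 um intervals from tip to shank).
#'
#' @inheritParams extractRegionSeries
#' @param startUm,stopUm,stepUm scan range and step, um.
#' @return named list of [RawSeries-class], one per centre.
#' @export
scanSeriesAlongTube <- function(ak, startUm = 1.5, stopUm = 21.5,
                                stepUm = 1.5, widthUm = 1.1,
                                stat = "median") {
  stopifnot(startUm < stopUm)
  centres <- seq(startUm, stopUm, by = stepUm)
  out <- lapply(centres, function(cc)
    extractRegionSeries(ak, cc, widthUm, stat))
  names(out) <- sprintf("%.1fum", centres)
  out
}
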