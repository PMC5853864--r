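#' @rdname accessors
#' @export
setMethod("intensityMatrix", "Kymograph", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("intensityMatrix", "AlignedKymograph", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("frameInterval", "Kymograph", function(x) x@dt)

#' @rdname accessors
#' @export
setMethod("frameInterval", "AlignedKymograph", function(x) x@dt)

#' @rdname accessors
#' @export
setMethod("pixelSize", "Kymograph", function(x) x@dx)

#' @rdname accessors
#' @export
setMethod("channelName", "Kymograph", function(x) x@channel)

#' @rdname accessors
#' @export
setMethod("sampleTimes", "RawSeries", function(x) x@t)

#' @rdname accessors
#' @export
setMethod("sampleTimes", "UniformSeries",
          function(x) x@t0 + (seq_along(x@v) - 1) * x@dt)

#' @rdname accessors
#' @export
setMethod("sampleTimes", "TipTrace", function(x) x@t)

#' @rdname accessors
#' @export
setMethod("seriesValues", "RawSeries", function(x) x@v)

#' @rdname accessors
#' @export
setMethod("seriesValues", "UniformSeries", function(x) x@v)

#' @rdname accessors
#' @export
setMethod("seriesUnits", "RawSeries", function(x) x@units)

#' @rdname accessors
#' @export
setMethod("seriesUnits", "UniformSeries", function(x) x@units)

#' @rdname accessors
#' @export
setMethod("frameInterval", "UniformSeries", function(x) x@dt)

#' @rdname accessors
#' @export
setMethod("tipPositions", "TipTrace", function(x) x@posPx)

#' Tip positions in micrometres
#' @param x a [TipTrace-class].
#' @return numeric vector, \code{tipPositions(x) * dx}.
#' @export
posUm <- function(x) {
  stopifnot(is(x, "TipTrace"))
  x@posPx * x@dx
}

#' @rdname accessors
#' @export
setMethod("distanceGrid", "AlignedKymograph", function(x) x@distUm)

#' @rdname accessors
#' @export
setMethod("backgroundCutoff", "BackgroundEstimate", function(x) x@cutoff)

#' @rdname accessors
#' @export
setMethod("wavePeriods", "CwtSpectrum", function(x) x@periods)

#' @rdname accessors
#' @export
setMethod("wavePeriods", "CrossSpectrum", function(x) x@periods)

#' @rdname accessors
#' @export
setMethod("wavePower", "CwtSpectrum", function(x) x@power)

#' @rdname accessors
#' @export
setMethod("wavePower", "CrossSpectrum", function(x) x@xpower)

#' @rdname accessors
#' @export
setMethod("coneOfInfluence", "CwtSpectrum", function(x) x@coi)

#' @rdname accessors
#' @export
setMethod("coneOfInfluence", "CrossSpectrum", function(x) x@coi)

#' @rdname accessors
#' @export
setMethod("significanceMask", "CwtSpectrum", function(x) x@signif)

#' @rdname accessors
#' @export
setMethod("significanceMask", "CrossSpectrum", function(x) x@signif)

#' @rdname accessors
#' @export
setMethod("phaseMatrix", "CrossSpectrum", function(x) x@phase)

#' @rdname accessors
#' @export
setMethod("ridgePoints", "RidgeSet", function(x) x@points)

#' @rdname accessors
#' @export
setMethod("mainComponent", "MixtureFit", function(x)
  list(mean = x@means[x@main], sd = x@sds[x@main], weight = x@weights[x@main]))

setMethod("show", "Kymograph", function(object) {
  cat(sprintf("Kymograph [%s]: %d frames x %d px, dt = %g s, dx = %g um%s\n",
              object@channel, nrow(object@values), ncol(object@values),
              object@dt, object@dx,
              if (object@flipped) " (flipped on import)" else ""))
})

setMethod("show", "RawSeries", function(object) {
  cat(sprintf("RawSeries: %d samples over [%g, %g] s%s\n",
              length(object@v), min(object@t), max(object@t),
              if (nzchar(object@units)) paste0(" [", object@units, "]") else ""))
})

setMethod("show", "UniformSeries", function(object) {
  cat(sprintf("UniformSeries: n = %d, t0 = %g s, dt = %g s%s\n",
              length(object@v), object@t0, object@dt,
              if (nzchar(object@units)) paste0(" [", object@units, "]") else ""))
})

setMethod("show", "TipTrace", function(object) {
  cat(sprintf("TipTrace (%s%s): %d frames, %d missing\n",
              object@method, if (object@smoothed) ", smoothed" else "",
              length(object@posPx), sum(is.na(object@posPx))))
})

setMethod("show", "AlignedKymograph", function(object) {
  cat(sprintf("AlignedKymograph: %d frames x %d bins, 0 - %.2f um from tip\n",
              nrow(object@values), ncol(object@values), max(object@distUm)))
})

setMethod("show", "BackgroundEstimate", function(object) {
  cat(sprintf("BackgroundEstimate: %d samples, cutoff %.4g at quantile %.2f\n",
              length(object@samples), object@cutoff, object@quantile))
})

setMethod("show", "MraDecomposition", function(object) {
  bands <- vapply(seq_along(object@details), function(j)
    sprintf("D%d (%g, %g] s", j, 2^j * object@dt, 2^(j + 1) * object@dt), "")
  cat(sprintf("MraDecomposition (%s): %d levels + smooth, n = %d\n",
              object@filter, length(object@details), length(object@smooth)))
  cat(" ", paste(bands, collapse = "; "), "\n")
})

setMethod("show", "CwtSpectrum", function(object) {
  cat(sprintf(
    "CwtSpectrum: %d scales (periods %.3g - %.3g s) x %d times%s\n",
    length(object@periods), min(object@periods), max(object@periods),
    length(object@times),
    if (is.na(object@alpha)) "" else sprintf(", tested at alpha = %g",
                                             object@alpha)))
})

setMethod("show", "CrossSpectrum", function(object) {
  cat(sprintf(
    "CrossSpectrum: %d scales (periods %.3g - %.3g s) x %d times%s\n",
    length(object@periods), min(object@periods), max(object@periods),
    length(object@times),
    if (is.na(object@alpha)) "" else sprintf(", tested at alpha = %g",
                                             object@alpha)))
})

setMethod("show", "RidgeSet", function(object) {
  cat(sprintf("RidgeSet: %d ridge points over %d trustworthy times\n",
              nrow(object@points), sum(object@coiTimes)))
})

setMethod("show", "MixtureFit", function(object) {
  cat("Two-component Gaussian mixture fit\n")
  for (k in 1:2)
    cat(sprintf("  comp %d%s: mean %.4g, sd %.4g, weight %.3f\n", k,
                if (k == object@main) " (main)" else "",
                object@means[k], object@sds[k], object@weights[k]))
  cat(sprintf("  loglik %.4g\n", object@loglik))
})

#' @export
setMethod("length", "RawSeries", function(x) length(x@v))

#' @export
setMethod("length", "UniformSeries", function(x) length(x@v))

#' @export
setMethod("length", "TipTrace", function(x) length(x@posPx))

#' @export
setMethod("dim", "Kymograph", function(x) dim(x@values))

#' @export
setMethod("dim", "AlignedKymograph", function(x) dim(x@values))
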