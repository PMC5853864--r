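#' Accessor generics
#'
#' Small accessor layer over the package's S4 containers: prefer these over
#' direct slot access.
#'
#' @param x an object of one of the kymowave classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname accessors
#' @export
setGeneric("seriesUnits", function(x) standardGeneric("seriesUnits"))

#' @rdname accessors
#' @export
setGeneric("tipPositions", function(x) standardGeneric("tipPositions"))

#' @rdname accessors
#' @export
setGeneric("distanceGrid", function(x) standardGeneric("distanceGrid"))

#' @rdname accessors
#' @export
setGeneric("backgroundCutoff", function(x) standardGeneric("backgroundCutoff"))

#' @rdname accessors
#' @export
setGeneric("wavePeriods", function(x) standardGeneric("wavePeriods"))

#' @rdname accessors
#' @export
setGeneric("wavePower", function(x) standardGeneric("wavePower"))

#' @rdname accessors
#' @export
setGeneric("coneOfInfluence", function(x) standardGeneric("coneOfInfluence"))

#' @rdname accessors
#' @export
setGeneric("significanceMask", function(x) standardGeneric("significanceMask"))

#' @rdname accessors
#' @export
setGeneric("phaseMatrix", function(x) standardGeneric("phaseMatrix"))

#' @rdname accessors
#' @export
setGeneric("ridgePoints", function(x) standardGeneric("ridgePoints"))

#' @rdname accessors
#' @export
setGeneric("mainComponent", function(x) standardGeneric("mainComponent"))

#' Test an observed wavelet spectrum against a red-noise null
#'
#' @param spec a [CwtSpectrum-class] or [CrossSpectrum-class].
#' @param alpha significance level (default 0.05).
#' @return the input object with its significance mask filled in.
#' @export
setGeneric("significance", function(spec, alpha = 0.05)
  standardGeneric("significance"))

#' Extract wavelet ridges (per-time power maxima)
#'
#' @param spec a significance-tested [CwtSpectrum-class] or
#'   [CrossSpectrum-class].
#' @param minPowerFrac keep only maxima with power at least this fraction of
#'   the global maximum (default 0.05).
#' @param maxPerTime at most this many ridges per time point (default 2).
#' @return a [RidgeSet-class].
#' @export
setGeneric("extractRidges",
  function(spec, minPowerFrac = 0.05, maxPerTime = 2)
    standardGeneric("extractRidges"))
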