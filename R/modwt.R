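#' Shift-invariant discrete wavelet multiresolution analysis
#'
#' A maximal-overlap (undecimated) discrete wavelet transform and its
#' additive multiresolution analysis, used as the pipeline's band-pass
#' filter: detail level j carries periods nominally in
#' (2^j dt, 2^(j+1) dt] seconds, the smooth carries the trend/baseline, and
#' details plus smooth reconstruct the input exactly. Works for arbitrary
#' series lengths; the boundary is handled by reflection.
#'
#' @name mra-module
NULL

.wave_filters <- list(
  haar = c(0.7071067811865475, 0.7071067811865475),
  d4 = c(0.4829629131445341, 0.8365163037378077,
         0.2241438680420134, -0.1294095225512603),
  la8 = c(-0.07576571478935668, -0.02963552764596039,
          0.49761866763256290, 0.80373875180538600,
          0.29785779560560505, -0.09921954357695636,
          -0.01260396726226383, 0.03222310060407815)
)

.modwt_filters <- function(filter) {
  g <- .wave_filters[[match.arg(filter, names(.wave_filters))]]
  L <- length(g)
  h <- (-1)^(seq_len(L) - 1) * rev(g)    # quadrature mirror
  list(g = g / sqrt(2), h = h / sqrt(2), L = L)
}

# circular filtering with the level-j upsampled filter:
# out[t] = sum_l f[l] x[(t - 2^(j-1) l) mod N]
.circ_filt <- function(x, f, j) {
  n <- length(x)
  step <- 2^(j - 1)
  out <- numeric(n)
  idx <- seq_len(n)
  for (l in seq_along(f)) {
    sh <- ((idx - 1 - step * (l - 1)) %% n) + 1
    out <- out + f[l] * x[sh]
  }
  out
}

# inverse one-stage: reconstruct V_{j-1} from (W_j, V_j):
# out[t] = sum_l h[l] W[(t + 2^(j-1) l) mod N] + sum_l g[l] V[...]
.circ_filt_inv <- function(x, f, j) {
  n <- length(x)
  step <- 2^(j - 1)
  out <- numeric(n)
  idx <- seq_len(n)
  for (l in seq_along(f)) {
    sh <- ((idx - 1 + step * (l - 1)) %% n) + 1
    out <- out + f[l] * x[sh]
  }
  out
}

.modwt_forward <- function(x, nLevels, flt) {
  W <- vector("list", nLevels)
  V <- x
  for (j in seq_len(nLevels)) {
    W[[j]] <- .circ_filt(V, flt$h, j)
    V <- .circ_filt(V, flt$g, j)
  }
  list(W = W, V = V)
}

# MRA detail level j: inverse cascade with only W_j non-zero
.modwt_detail <- function(W, j, flt) {
  n <- length(W[[j]])
  D <- .circ_filt_inv(W[[j]], flt$h, j)
  if (j > 1) for (k in (j - 1):1) D <- .circ_filt_inv(D, flt$g, k)
  D
}

.modwt_smooth <- function(V, nLevels, flt) {
  S <- V
  for (k in nLevels:1) S <- .circ_filt_inv(S, flt$g, k)
  S
}

#' Multiresolution analysis of a uniform series
#'
#' @param us a [UniformSeries-class] with \code{n >= 2^nLevels}.
#' @param nLevels decomposition depth J (default: as deep as the series
#'   allows, capped at 6).
#' @param filter \code{"la8"} (default, 8-tap least-asymmetric),
#'   \code{"d4"} or \code{"haar"}.
#' @return an [MraDecomposition-class]; \code{sum(details) + smooth}
#'   reproduces the input to numerical precision.
#' @export
mra <- function(us, nLevels = NULL, filter = "la8") {
  stopifnot(is(us, "UniformSeries"))
  x <- us@v
  n <- length(x)
  if (is.null(nLevels)) nLevels <- max(1L, min(6L, floor(log2(n)) - 2L))
  if (2^nLevels > n)
    stop("nLevels too deep: need n >= 2^nLevels")
  flt <- .modwt_filters(filter)
  xe <- c(x, rev(x))                     # reflection boundary
  fwd <- .modwt_forward(xe, nLevels, flt)
  details <- lapply(seq_len(nLevels), function(j)
    .modwt_detail(fwd$W, j, flt)[seq_len(n)])
  smooth <- .modwt_smooth(fwd$V, nLevels, flt)[seq_len(n)]
  new("MraDecomposition", details = details, smooth = smooth, dt = us@dt,
      filter = filter)
}

#' Band selection from an MRA decomposition
#'
#' Detail level j is kept when its nominal period band
#' (2^j dt, 2^(j+1) dt] lies inside \code{[periodMin, periodMax]}; with
#' dt = 4 s the band 16-128 s selects levels 2-4 and 8-128 s selects levels
#' 1-4. The excluded smooth (trend/baseline) is returned alongside so that
#' baseline analyses can use it.
#'
#' @param d an [MraDecomposition-class].
#' @param periodMin,periodMax period band to keep, seconds.
#' @param keepTrend include the smooth in the filtered series
#'   (default FALSE, i.e. detrend).
#' @param t0 time of the first sample for the returned series (default 0).
#' @param units unit label.
#' @return list with \code{filtered} and \code{trend}
#'   ([UniformSeries-class]) and \code{levels} (integer vector of selected
#'   detail levels).
#' @export
bandpass <- function(d, periodMin, periodMax, keepTrend = FALSE, t0 = 0,
                     units = "") {
  stopifnot(is(d, "MraDecomposition"), periodMin < periodMax)
  J <- length(d@details)
  lev <- which(vapply(seq_len(J), function(j)
    2^j * d@dt >= periodMin && 2^(j + 1) * d@dt <= periodMax, logical(1)))
  if (length(lev) == 0L)
    stop("no detail level falls inside [", periodMin, ", ", periodMax, "] s")
  filt <- Reduce(`+`, d@details[lev])
  trend <- d@smooth
  # coarser-than-band details belong to the baseline side
  coarser <- setdiff(seq_len(J), lev)
  coarser <- coarser[coarser > max(lev)]
  if (length(coarser) > 0L) trend <- trend + Reduce(`+`, d@details[coarser])
  if (keepTrend) filt <- filt + trend
  list(filtered = UniformSeries(filt, dt = d@dt, t0 = t0, units = units),
       trend = UniformSeries(trend, dt = d@dt, t0 = t0, units = units),
       levels = lev)
}

#' Band-filter a uniform series in one call
#'
#' Convenience wrapper: [mra()] then [bandpass()], preserving the series'
#' time base and units.
#'
#' @param us a [UniformSeries-class].
#' @inheritParams bandpass
#' @inheritParams mra
#' @return as [bandpass()].
#' @export
bandFilter <- function(us, periodMin, periodMax, keepTrend = FALSE,
                       nLevels = NULL, filter = "la8") {
  d <- mra(us, nLevels = nLevels, filter = filter)
  bandpass(d, periodMin, periodMax, keepTrend = keepTrend, t0 = us@t0,
           units = us@units)
}
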