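#' 2-D multiresolution filtering of single-channel kymographs
#'
#' An undecimated separable wavelet multiresolution decomposition of the
#' kymograph image ("a trous" scheme, B3-spline scaling kernel, symmetric
#' boundary): the image is split into dyadic detail planes plus a smooth,
#' which sum back to the input exactly. Reconstructing without the finest
#' planes removes pixel noise and thin stripe/kink artefacts; without the
#' coarsest planes and smooth it removes photobleaching drift, refocusing
#' blocks and other slow trends — recovering oscillatory signal that is
#' otherwise masked in single-channel kymographs.
#'
#' @name filter2d
NULL

# separable smoothing with the level-j upsampled B3-spline kernel
# (1,4,6,4,1)/16, symmetric boundary extension
.atrous_smooth <- function(m, j) {
  kern <- c(1, 4, 6, 4, 1) / 16
  step <- 2^(j - 1)
  offs <- (-2:2) * step
  reflect <- function(i, n) {
    # symmetric (mirror) index fold into 1..n
    i <- (i - 1) %% (2 * n)
    ifelse(i < n, i + 1, 2 * n - i)
  }
  smoothDim <- function(m, along) {
    n <- if (along == 1) nrow(m) else ncol(m)
    out <- m * 0
    for (k in seq_along(offs)) {
      idx <- reflect(seq_len(n) + offs[k], n)
      out <- out + kern[k] *
        (if (along == 1) m[idx, , drop = FALSE]
         else m[, idx, drop = FALSE])
    }
    out
  }
  smoothDim(smoothDim(m, 1), 2)
}

#' Multiresolution filter for a kymograph image
#'
#' Decomposes the intensity matrix into \code{nLevels} detail planes
#' \code{D_j = S_(j-1) - S_j} (finest first) plus the smooth \code{S_J},
#' then reconstructs omitting the finest \code{dropFine} planes and — when
#' \code{dropCoarse > 0} — the coarsest \code{dropCoarse} planes together
#' with the smooth. \code{dropFine = 0, dropCoarse = 0} returns the input
#' unchanged (perfect reconstruction).
#'
#' @param kymo a [Kymograph-class].
#' @param dropFine number of finest detail planes to drop (default 1).
#' @param dropCoarse number of coarsest detail planes to drop, together
#'   with the smooth (default 1).
#' @param nLevels decomposition depth (default: as deep as the smaller
#'   image dimension allows, capped at 6).
#' @return the filtered [Kymograph-class] (same shape and calibration).
#' @export
filterKymograph2d <- function(kymo, dropFine = 1, dropCoarse = 1,
                              nLevels = NULL) {
  stopifnot(is(kymo, "Kymograph"))
  m <- kymo@values
  if (is.null(nLevels))
    nLevels <- max(2L, min(6L, floor(log2(min(dim(m)))) - 2L))
  if (dropFine + dropCoarse >= nLevels + (dropCoarse == 0))
    stop("dropped levels exceed the decomposition depth")
  S <- m
  details <- vector("list", nLevels)
  for (j in seq_len(nLevels)) {
    Sj <- .atrous_smooth(S, j)
    details[[j]] <- S - Sj
    S <- Sj
  }
  keep <- setdiff(seq_len(nLevels),
                  c(seq_len(dropFine),
                    if (dropCoarse > 0)
                      (nLevels - dropCoarse + 1L):nLevels))
  out <- Reduce(`+`, details[keep], accumulate = FALSE)
  if (is.null(out)) out <- m * 0
  if (dropCoarse == 0) out <- out + S
  Kymograph(out, dt = kymo@dt, dx = kymo@dx,
            channel = paste0(kymo@channel, "_filtered"), normalize = FALSE)
}
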