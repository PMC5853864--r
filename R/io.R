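#' Construct a Kymograph
#'
#' Applies orientation normalization: if, on the first frame, the mean
#' intensity of the last 10\% of columns exceeds that of the first 10\%, the
#' column order is reversed so the cell sits at low column indices.
#'
#' @param values numeric matrix, frames (rows) x pixels (columns).
#' @param dt frame interval, seconds.
#' @param dx pixel size, micrometres.
#' @param channel channel label.
#' @param normalize apply orientation normalization (default TRUE).
#' @return a [Kymograph-class].
#' @export
Kymograph <- function(values, dt, dx, channel = "raw", normalize = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  flipped <- FALSE
  if (normalize && ncol(values) >= 2L) {
    k <- max(1L, floor(0.1 * ncol(values)))
    first <- mean(values[1L, seq_len(k)], na.rm = TRUE)
    last <- mean(values[1L, ncol(values) - seq_len(k) + 1L], na.rm = TRUE)
    if (last > first) {
      values <- values[, rev(seq_len(ncol(values))), drop = FALSE]
      flipped <- TRUE
    }
  }
  new("Kymograph", values = unname(values), dt = dt, dx = dx,
      channel = channel, flipped = flipped)
}

#' Construct a RawSeries
#'
#' @param t sample times, seconds.
#' @param v values.
#' @param units unit label.
#' @param collapse collapse duplicate timestamps by their mean and sort by
#'   time (default TRUE).
#' @return a [RawSeries-class].
#' @export
RawSeries <- function(t, v, units = "", collapse = TRUE) {
  keep <- is.finite(t) & !is.na(v)
  t <- t[keep]; v <- v[keep]
  if (collapse) {
    o <- order(t)
    t <- t[o]; v <- v[o]
    if (anyDuplicated(t)) {
      v <- as.numeric(tapply(v, t, mean))
      t <- sort(unique(t))
    }
  }
  new("RawSeries", t = as.numeric(t), v = as.numeric(v), units = units)
}

#' Construct a UniformSeries
#'
#' @param v values.
#' @param dt sampling interval, seconds.
#' @param t0 time of the first sample, seconds (default 0).
#' @param units unit label.
#' @return a [UniformSeries-class].
#' @export
UniformSeries <- function(v, dt, t0 = 0, units = "") {
  new("UniformSeries", v = as.numeric(v), dt = dt, t0 = t0, units = units)
}

#' Coerce a UniformSeries to a RawSeries
#' @param us a [UniformSeries-class].
#' @return a [RawSeries-class] on the implied time grid.
#' @export
asRawSeries <- function(us) {
  stopifnot(is(us, "UniformSeries"))
  RawSeries(sampleTimes(us), us@v, units = us@units, collapse = FALSE)
}

#' Read a kymograph from TIFF or CSV
#'
#' CSV files are read as plain numeric matrices (no header); TIFF as
#' single-channel grayscale, keeping the stored sample values (16-bit counts
#' stay integer-valued). ImageJ kymographs exported with space on the rows
#' are auto-transposed when \code{nFrames} identifies the time dimension;
#' otherwise rows are assumed to be frames.
#'
#' @param path file path (.tif/.tiff or .csv).
#' @param dt frame interval, seconds.
#' @param dx pixel size, micrometres.
#' @param channel channel label.
#' @param nFrames optional expected number of frames, used to auto-detect a
#'   transposed matrix.
#' @return an orientation-normalized [Kymograph-class]; whether the columns
#'   were flipped is recorded in its \code{flipped} slot.
#' @export
readKymograph <- function(path, dt, dx, channel = "raw", nFrames = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3L) {
      if (dim(img)[3] != 1L)
        stop("only single-channel grayscale TIFF is supported")
      img <- img[, , 1L]
    }
    m <- unclass(img)
  } else {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("non-numeric or missing content in ", path)
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L)
    stop("empty matrix in ", path)
  if (!is.null(nFrames) && ncol(m) == nFrames && nrow(m) != nFrames)
    m <- t(m)
  Kymograph(m, dt = dt, dx = dx, channel = channel)
}

#' Write a kymograph to TIFF or CSV
#'
#' Integer-valued kymographs (the native case for microscope data) are
#' written as 16-bit grayscale TIFF and round-trip bit-exactly through
#' [readKymograph()]. Real-valued matrices must go to CSV (value-preserving
#' to working precision).
#'
#' @param kymo a [Kymograph-class].
#' @param path destination (.tif/.tiff or .csv).
#' @return the path, invisibly.
#' @export
writeKymograph <- function(kymo, path) {
  stopifnot(is(kymo, "Kymograph"))
  v <- kymo@values
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (any(v != round(v)) || any(v < 0) || any(v > 65535))
      stop("TIFF output requires integer values in [0, 65535]; use CSV")
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  } else {
    utils::write.table(v, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a time series from CSV
#'
#' @param path CSV file with a header row.
#' @param timeCol,valueCol column names for time (seconds) and value.
#' @param units unit label attached to the result.
#' @return a [RawSeries-class], sorted by time, duplicate timestamps
#'   collapsed by their mean.
#' @export
readSeries <- function(path, timeCol = "time_s", valueCol = "value",
                       units = "") {
  d <- utils::read.csv(path)
  if (!all(c(timeCol, valueCol) %in% names(d)))
    stop("columns '", timeCol, "' and '", valueCol, "' required in ", path)
  t <- as.numeric(d[[timeCol]]); v <- as.numeric(d[[valueCol]])
  if (any(is.na(t))) stop("non-numeric time values in ", path)
  rs <- RawSeries(t, v, units = units)
  if (length(rs) < 4L) stop("need at least 4 samples, got ", length(rs))
  rs
}

#' Write a time series to CSV
#'
#' @param x a [RawSeries-class] or [UniformSeries-class].
#' @param path destination CSV.
#' @param valueCol name for the value column.
#' @return the path, invisibly.
#' @export
writeSeries <- function(x, path, valueCol = "value") {
  d <- data.frame(time_s = sampleTimes(x), value = seriesValues(x))
  names(d)[2] <- valueCol
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an externally produced tip-tracking trace
#'
#' For method comparison with template-matching trackers whose traces are
#' exported to CSV (columns \code{frame}, \code{position_px}).
#'
#' @param path CSV file.
#' @param dt frame interval, seconds.
#' @param dx pixel size, micrometres.
#' @return a [TipTrace-class] with method \code{"external"}.
#' @export
readTipTrace <- function(path, dt, dx) {
  d <- utils::read.csv(path)
  if (!all(c("frame", "position_px") %in% names(d)))
    stop("columns 'frame' and 'position_px' required in ", path)
  o <- order(d$frame)
  new("TipTrace", t = as.numeric(d$frame[o]) * dt,
      posPx = as.numeric(d$position_px[o]), dx = dx,
      method = "external", smoothed = FALSE)
}

#' Write a tip trace to CSV
#'
#' @param trace a [TipTrace-class].
#' @param path destination CSV.
#' @return the path, invisibly.
#' @export
writeTipTrace <- function(trace, path) {
  utils::write.csv(
    data.frame(time_s = trace@t, position_px = trace@posPx,
               position_um = posUm(trace)),
    path, row.names = FALSE)
  invisible(path)
}

#' Write a ridge table to CSV
#'
#' Columns: \code{time_s}, \code{period_s}, \code{power}, \code{amplitude}
#' (plus \code{phase}, \code{delay_s} when present).
#'
#' @param ridges a [RidgeSet-class] or a ridge/delay data.frame.
#' @param path destination CSV.
#' @return the path, invisibly.
#' @export
writeRidgeTable <- function(ridges, path) {
  d <- if (is(ridges, "RidgeSet")) ridges@points else as.data.frame(ridges)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
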