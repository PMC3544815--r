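#' Serialize an LNP cell to JSON
#'
#' Writes the spatial weights (row-major), temporal basis coefficients, the
#' basis configuration, the nonlinearity and metadata as a JSON object that
#' \code{\link{readCellJSON}} reconstructs exactly.
#'
#' @param cell an \linkS4class{LNPCell}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCellJSON <- function(cell, path) {
  nl <- cell@nonlinearity
  obj <- list(
    cellId = cell@cellId, polarity = cell@polarity,
    rfCenter = cell@rfCenter,
    spatialWeights = cell@spatialWeights,
    temporalCoeffs = cell@temporalCoeffs,
    basis = list(nBasis = nrow(cell@basis@basis),
                 nBins = ncol(cell@basis@basis),
                 binWidth = cell@basis@binWidth,
                 stretch = cell@basis@stretch),
    nonlinearity = list(kind = nl@kind, gain = nl@gain, offset = nl@offset,
                        knots = nl@knots, values = nl@values,
                        rateFloor = nl@rateFloor))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read an LNP cell from JSON
#'
#' @param path file written by \code{\link{writeCellJSON}}.
#' @return an \linkS4class{LNPCell}
#' @export
readCellJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nl <- obj$nonlinearity
  nonlin <- if (nl$kind == "exponential")
    exponentialNonlinearity(nl$gain, nl$offset, nl$rateFloor)
  else
    splineNonlinearity(nl$knots, nl$values, nl$rateFloor)
  basis <- raisedCosineBasis(obj$basis$nBasis, obj$basis$nBins,
                             obj$basis$binWidth, obj$basis$stretch)
  lnpCell(matrix(obj$spatialWeights, 10, 10), obj$temporalCoeffs, nonlin,
          rfCenter = obj$rfCenter, basis = basis, polarity = obj$polarity,
          cellId = obj$cellId)
}

#' Write a spike raster as CSV
#'
#' Columns \code{trial} and \code{spike_time_s}, preceded by a comment line
#' carrying the duration and cell id so the raster round-trips.
#'
#' @param raster a \linkS4class{SpikeRaster}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRasterCSV <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration=%.17g cellId=%s nTrials=%d",
                     raster@duration, raster@cellId,
                     length(raster@trials)), con)
  df <- data.frame(
    trial = rep(seq_along(raster@trials),
                vapply(raster@trials, length, integer(1))),
    spike_time_s = unlist(raster@trials))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a spike raster from CSV
#'
#' @param path file written by \code{\link{writeRasterCSV}}.
#' @return a \linkS4class{SpikeRaster}
#' @export
readRasterCSV <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec(
    "^# duration=([0-9.eE+-]+) cellId=(\\S+) nTrials=([0-9]+)", hdr))[[1]]
  if (length(m) != 4) stop("not a raster CSV written by writeRasterCSV")
  duration <- as.numeric(m[2]); cellId <- m[3]; nTrials <- as.integer(m[4])
  df <- read.csv(path, comment.char = "#")
  trials <- lapply(seq_len(nTrials), function(i)
    sort(df$spike_time_s[df$trial == i]))
  new("SpikeRaster", trials = trials, duration = duration, cellId = cellId)
}
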