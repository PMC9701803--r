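#' Read and write rasters as ESRI ASCII grids
#'
#' Plain-text single-band raster exchange on the package's north-up WGS84
#' lon/lat grid convention. On disk, nodata is the sentinel \code{-9999};
#' in memory it is NA. Values are serialized with full double precision so
#' a write/read round trip reproduces grid and values bit-exactly.
#'
#' @param path file path of the `.asc` grid.
#' @return `readRaster` returns an \linkS4class{AgRaster};
#'   `writeRaster` invisibly returns `path`.
#' @name raster-io
NULL

#' @rdname raster-io
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, n = 6L)
  kv <- strsplit(trimws(lines), "[[:space:]]+")
  keys <- tolower(vapply(kv, `[`, character(1L), 1L))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1L), 2L)))
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% keys) || anyNA(vals[need]))
    stop("malformed ASCII grid header in ", path)
  if (!("xllcorner" %in% keys && "yllcorner" %in% keys))
    stop("only corner-registered (xllcorner/yllcorner) grids are supported")
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  body <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(body) != nr * nc)
    stop("ASCII grid body has ", length(body), " values, expected ", nr * nc)
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  agRaster(m, xmin = vals[["xllcorner"]],
           ymax = vals[["yllcorner"]] + nr * vals[["cellsize"]],
           res = vals[["cellsize"]])
}

#' @rdname raster-io
#' @param x an \linkS4class{AgRaster} to write.
#' @export
writeRaster <- function(x, path) {
  stopifnot(is(x, "AgRaster"))
  d <- dim(x@values)
  hdr <- c(sprintf("ncols %d", d[2L]),
           sprintf("nrows %d", d[1L]),
           sprintf("xllcorner %.17g", x@xmin),
           sprintf("yllcorner %.17g", x@ymax - d[1L] * x@res),
           sprintf("cellsize %.17g", x@res),
           sprintf("NODATA_value %d", NODATA_SENTINEL))
  v <- x@values
  v[is.na(v)] <- NODATA_SENTINEL
  rows <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Spherical pixel area
#'
#' Area in m2 of a square lon/lat cell, from the spherical cell geometry
#' scaled by the cosine of the cell-center latitude (authalic Earth radius
#' 6371008.8 m).
#'
#' @param latDeg cell-center latitude(s), degrees.
#' @param cellSizeDeg cell size in degrees.
#' @return area(s) in m2.
#' @export
pixelAreaM2 <- function(latDeg, cellSizeDeg) {
  R <- 6371008.8
  (R * pi / 180 * cellSizeDeg)^2 * cos(latDeg * pi / 180)
}
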