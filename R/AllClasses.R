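#' @import methods
NULL

NODATA_SENTINEL <- -9999

#' Single-band geographic raster
#'
#' A 2-D grid of values on a north-up, pixel-is-area WGS84 lon/lat grid.
#' Row 1 is the northernmost row; missing data are IEEE NaN/NA in memory and
#' the sentinel \code{-9999} on disk. Carries NDVI, LSWI, GPP, masks and
#' district labels throughout the package.
#'
#' @slot values numeric matrix of cell values (row 1 = north).
#' @slot xmin western edge of the grid (degrees longitude).
#' @slot ymax northern edge of the grid (degrees latitude).
#' @slot res square cell size in degrees.
#'
#' @aliases AgRaster-class
#' @exportClass AgRaster
setClass("AgRaster",
  representation(values = "matrix", xmin = "numeric", ymax = "numeric",
                 res = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@values))
      msg <- c(msg, "'values' must be a numeric matrix")
    if (length(object@res) != 1L || !is.finite(object@res) || object@res <= 0)
      msg <- c(msg, "'res' must be a single positive number")
    if (length(object@xmin) != 1L || length(object@ymax) != 1L ||
        !is.finite(object@xmin) || !is.finite(object@ymax))
      msg <- c(msg, "'xmin' and 'ymax' must be single finite numbers")
    if (length(msg)) msg else TRUE
  })

#' Construct an AgRaster
#'
#' @param values numeric matrix (row 1 is the northernmost row).
#' @param xmin,ymax western / northern grid edges in degrees (WGS84).
#' @param res cell size in degrees.
#' @return an \linkS4class{AgRaster}.
#' @examples
#' r <- agRaster(matrix(1:6, 2, 3), xmin = 75, ymax = 22, res = 0.005)
#' gridDims(r)
#' @export
agRaster <- function(values, xmin = 0, ymax = 0, res = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("AgRaster", values = values, xmin = xmin, ymax = ymax, res = res)
}

#' @describeIn agRaster matrix of cell values.
#' @param x an AgRaster.
#' @export
rasterValues <- function(x) {
  stopifnot(is(x, "AgRaster"))
  x@values
}

#' @describeIn agRaster c(nrow, ncol) of the grid.
#' @export
gridDims <- function(x) {
  stopifnot(is(x, "AgRaster") || is(x, "CompositeStack"))
  if (is(x, "CompositeStack")) x <- x@layers[[1L]]
  dim(x@values)
}

#' @describeIn agRaster cell size in degrees.
#' @export
cellSize <- function(x) {
  stopifnot(is(x, "AgRaster"))
  x@res
}

#' @describeIn agRaster replace the value matrix, keeping the grid.
#' @param newValues replacement matrix of identical dimensions.
#' @export
setRasterValues <- function(x, newValues) {
  stopifnot(is(x, "AgRaster"), all(dim(newValues) == dim(x@values)))
  newValues <- as.matrix(newValues)
  storage.mode(newValues) <- "double"
  x@values <- newValues
  x
}

#' Latitudes and longitudes of cell centers
#'
#' @param x an \linkS4class{AgRaster}.
#' @return list with `lat` (length nrow, north to south) and `lon`
#'   (length ncol, west to east) of cell centers in degrees.
#' @export
cellCenters <- function(x) {
  stopifnot(is(x, "AgRaster"))
  d <- dim(x@values)
  list(lat = x@ymax - (seq_len(d[1L]) - 0.5) * x@res,
       lon = x@xmin + (seq_len(d[2L]) - 0.5) * x@res)
}

#' Do two rasters share the same grid?
#'
#' Same dimensions, origin and cell size (to 1e-9 degrees).
#' @param a,b AgRaster objects.
#' @return logical.
#' @export
compatibleGrid <- function(a, b) {
  stopifnot(is(a, "AgRaster"), is(b, "AgRaster"))
  all(dim(a@values) == dim(b@values)) &&
    abs(a@xmin - b@xmin) < 1e-9 &&
    abs(a@ymax - b@ymax) < 1e-9 &&
    abs(a@res - b@res) < 1e-9
}

setMethod("show", "AgRaster", function(object) {
  d <- dim(object@values)
  v <- object@values[is.finite(object@values)]
  cat(sprintf("AgRaster: %d x %d cells, %.6g deg resolution\n", d[1L], d[2L],
              object@res))
  cat(sprintf("  extent : lon [%.6g, %.6g], lat [%.6g, %.6g]\n",
              object@xmin, object@xmin + d[2L] * object@res,
              object@ymax - d[1L] * object@res, object@ymax))
  if (length(v))
    cat(sprintf("  values : [%.6g, %.6g], %d nodata cells\n",
                min(v), max(v), sum(!is.finite(object@values))))
  else cat("  values : all nodata\n")
})

#' Ordered stack of co-registered 16-day composites
#'
#' An ordered sequence of \linkS4class{AgRaster} layers on one grid, one
#' layer per 16-day compositing window within a season, with the window
#' start dates attached.
#'
#' @slot layers list of AgRaster layers.
#' @slot startDates Date vector of window start dates (strictly increasing,
#'   16-day spacing).
#' @slot varname character variable name (e.g. "NDVI").
#' @slot units character units string.
#'
#' @aliases CompositeStack-class
#' @exportClass CompositeStack
setClass("CompositeStack",
  representation(layers = "list", startDates = "Date", varname = "character",
                 units = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@layers)
    if (n == 0L) msg <- c(msg, "stack must contain at least one layer")
    if (!all(vapply(object@layers, is, logical(1L), "AgRaster")))
      msg <- c(msg, "all layers must be AgRaster objects")
    else if (n > 1L) {
      ok <- vapply(object@layers[-1L], compatibleGrid, logical(1L),
                   b = object@layers[[1L]])
      if (!all(ok)) msg <- c(msg, "layers must be co-registered")
    }
    if (length(object@startDates) != n)
      msg <- c(msg, "one start date per layer required")
    if (n > 1L && length(object@startDates) == n) {
      dd <- diff(as.integer(object@startDates))
      if (!all(dd == 16L))
        msg <- c(msg, "start dates must increase in 16-day steps")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a CompositeStack
#'
#' @param layers list of co-registered \linkS4class{AgRaster} layers.
#' @param startDates Date vector of 16-day window start dates.
#' @param varname,units variable name and units.
#' @return a \linkS4class{CompositeStack}.
#' @export
compositeStack <- function(layers, startDates, varname = "", units = "") {
  new("CompositeStack", layers = layers, startDates = as.Date(startDates),
      varname = varname, units = units)
}

#' @describeIn compositeStack number of layers.
#' @param x a CompositeStack.
#' @export
nLayers <- function(x) {
  stopifnot(is(x, "CompositeStack"))
  length(x@layers)
}

#' @describeIn compositeStack extract layer i as an AgRaster.
#' @param i layer index.
#' @export
getLayer <- function(x, i) {
  stopifnot(is(x, "CompositeStack"))
  x@layers[[i]]
}

#' @describeIn compositeStack window start dates.
#' @export
startDates <- function(x) {
  stopifnot(is(x, "CompositeStack"))
  x@startDates
}

#' @describeIn compositeStack values as an nrow x ncol x nlayer array.
#' @export
stackValues <- function(x) {
  stopifnot(is(x, "CompositeStack"))
  d <- dim(x@layers[[1L]]@values)
  arr <- array(NA_real_, c(d, length(x@layers)))
  for (i in seq_along(x@layers)) arr[, , i] <- x@layers[[i]]@values
  arr
}

setMethod("show", "CompositeStack", function(object) {
  d <- dim(object@layers[[1L]]@values)
  cat(sprintf("CompositeStack '%s' [%s]: %d layers of %d x %d cells\n",
              object@varname, object@units, length(object@layers),
              d[1L], d[2L]))
  cat(sprintf("  windows: %s .. %s (16-day)\n",
              format(min(object@startDates)), format(max(object@startDates))))
})
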