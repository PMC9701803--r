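#' @keywords internal
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Fraction of PAR absorbed by chlorophyll from NDVI
#'
#' Linear NDVI relation \eqn{fPAR = a \cdot NDVI - b} (radiative-transfer
#' based), clamped to [0, 1]: the raw linear form goes negative below
#' NDVI = b/a, which would make GPP negative on sparse canopies.
#' NA/NaN inputs (nodata) pass through.
#'
#' @param ndvi numeric vector/matrix in [-1, 1] (NA allowed).
#' @param params an \linkS4class{FparParams}.
#' @return fPAR values in [0, 1], same shape as `ndvi`.
#' @examples
#' computeFpar(0.5)   # 1.24 * 0.5 - 0.168 = 0.452
#' @export
computeFpar <- function(ndvi, params = fparParams()) {
  stopifnot(is(params, "FparParams"))
  bad <- !is.na(ndvi) & (ndvi < -1 | ndvi > 1)
  if (any(bad)) stop("NDVI outside [-1, 1]")
  out <- clamp01(params@a * ndvi - params@b)
  if (is.matrix(ndvi)) dim(out) <- dim(ndvi)
  out
}

#' Land surface water index from NIR and SWIR reflectance
#'
#' \eqn{LSWI = (NIR - SWIR)/(NIR + SWIR)}, a canopy-water-content index
#' from the NIR (841-876 nm) and SWIR (1628-1652 nm) bands.
#' Pixels where NIR + SWIR = 0 are undefined and return NA.
#'
#' @param nir,swir nonnegative reflectances (NA allowed).
#' @return LSWI in [-1, 1], NA where undefined.
#' @export
computeLswi <- function(nir, swir) {
  if (any(!is.na(nir) & nir < 0) || any(!is.na(swir) & swir < 0))
    stop("reflectances must be nonnegative")
  s <- nir + swir
  out <- ifelse(!is.na(s) & s == 0, NA_real_, (nir - swir) / s)
  if (is.matrix(nir)) dim(out) <- dim(nir)
  out
}

#' Water down-regulation scalar
#'
#' \eqn{W = (1 + LSWI) / (1 + LSWI_{max})}, clamped to [0, 1], where
#' LSWImax is the per-pixel seasonal maximum LSWI. Degenerate pixels with
#' LSWImax = -1 return NA.
#'
#' @param lswi,lswiMax values in [-1, 1] (NA allowed).
#' @return W scalar in [0, 1], same shape as `lswi`.
#' @export
computeWscalar <- function(lswi, lswiMax) {
  bad <- function(x) !is.na(x) & (x < -1 | x > 1)
  if (any(bad(lswi)) || any(bad(lswiMax)))
    stop("LSWI values outside [-1, 1]")
  den <- 1 + lswiMax
  out <- ifelse(!is.na(den) & den == 0, NA_real_, clamp01((1 + lswi) / den))
  if (is.matrix(lswi)) dim(out) <- dim(lswi)
  out
}

#' Temperature down-regulation scalar
#'
#' \deqn{T_{scalar} = \frac{(T - T_{max})(T - T_{min})}
#'   {(T - T_{max})(T - T_{min}) - (T - T_{opt})^2}}
#' set to 0 wherever \eqn{T \le T_{min}} or \eqn{T \ge T_{max}} (the raw
#' formula is negative or exceeds 1 outside the cardinal range, consistent
#' with published VPM practice). The scalar equals 1 exactly at Topt.
#'
#' @param t daytime mean air temperature, degC (NA allowed).
#' @param params a \linkS4class{PathwayParams}.
#' @return T scalar in [0, 1], same shape as `t`.
#' @export
computeTscalar <- function(t, params = c3Params()) {
  stopifnot(is(params, "PathwayParams"))
  num <- (t - params@tMax) * (t - params@tMin)
  den <- num - (t - params@tOpt)^2
  out <- num / den
  out[!is.na(t) & (t <= params@tMin | t >= params@tMax)] <- 0
  out <- clamp01(out)
  if (is.matrix(t)) dim(out) <- dim(t)
  out
}

#' Pixel maximum light-use efficiency from C3/C4 crop fractions
#'
#' \eqn{\varepsilon^* = LUE_{C3} \cdot prop_{C3} + LUE_{C4} \cdot prop_{C4}},
#' the convex combination of the pathway maxima weighted by the fractions of
#' C3 and C4 crops in the pixel.
#'
#' @param propC3,propC4 nonnegative fractions summing to 1 (tolerance 1e-6;
#'   NA allowed, jointly).
#' @param lueC3,lueC4 pathway maximum light-use efficiencies (gC/MJ APAR).
#' @return epsilon-star in gC/MJ APAR, same shape as `propC3`.
#' @export
computeLueMax <- function(propC3, propC4, lueC3 = 1.388, lueC4 = 1.542) {
  ok <- !is.na(propC3) & !is.na(propC4)
  if (any(propC3[ok] < 0) || any(propC4[ok] < 0))
    stop("crop fractions must be nonnegative")
  if (any(abs(propC3[ok] + propC4[ok] - 1) > 1e-6))
    stop("propC3 + propC4 must equal 1 (tolerance 1e-6)")
  out <- lueC3 * propC3 + lueC4 * propC4
  if (is.matrix(propC3)) dim(out) <- dim(propC3)
  out
}

#' GPP of one 16-day composite
#'
#' Element-wise VPM step: \eqn{GPP = \varepsilon \cdot fPAR \cdot PAR} with
#' \eqn{\varepsilon = \varepsilon^* T_{scalar} W_{scalar} P_{scalar}} and
#' \eqn{P_{scalar} = 1}. The temperature scalar is evaluated under both the
#' C3 and C4 parameter sets and mixed with the same propC3/propC4 weights
#' as the light-use-efficiency maximum (mixed pixels have no single
#' pathway temperature response). Nodata (NA) in any driver propagates.
#'
#' @param ndvi,lswi,lswiMax,par16d,tday,propC3,propC4 co-shaped numeric
#'   vectors/matrices: NDVI, composite LSWI, seasonal max LSWI, PAR summed
#'   over the window (MJ/m2), daytime mean temperature (degC), pathway
#'   fractions.
#' @param params a "VpmParams" bundle, see [vpmParams()].
#' @return GPP in gC/m2 per composite (>= 0 or NA), same shape as inputs.
#' @export
computeGppComposite <- function(ndvi, lswi, lswiMax, par16d, tday,
                                propC3, propC4, params = vpmParams()) {
  stopifnot(inherits(params, "VpmParams"))
  fpar <- computeFpar(ndvi, params$fpar)
  wsc <- computeWscalar(lswi, lswiMax)
  tsc <- propC3 * computeTscalar(tday, params$c3) +
         propC4 * computeTscalar(tday, params$c4)
  eps <- computeLueMax(propC3, propC4, params$c3@lueMax, params$c4@lueMax) *
         tsc * wsc * params$pScalar
  out <- eps * fpar * par16d
  if (is.matrix(ndvi)) dim(out) <- dim(ndvi)
  out
}

#' Per-pixel seasonal maximum LSWI
#'
#' Maximum LSWI across the composites of a season, ignoring nodata; pixels
#' that are nodata in every composite stay nodata.
#'
#' @param lswiStack a \linkS4class{CompositeStack} of LSWI layers.
#' @return an \linkS4class{AgRaster} of LSWImax.
#' @export
computeLswiMax <- function(lswiStack) {
  stopifnot(is(lswiStack, "CompositeStack"))
  arr <- stackValues(lswiStack)
  mx <- apply(arr, c(1L, 2L), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) max(v) else NA_real_
  })
  setRasterValues(getLayer(lswiStack, 1L), mx)
}

#' Run the VPM step over every composite of a scene
#'
#' Convenience wrapper producing the GPP \linkS4class{CompositeStack} from
#' co-registered driver stacks; LSWImax is computed from the LSWI stack.
#'
#' @param ndviStack,lswiStack,parStack,tdayStack driver
#'   \linkS4class{CompositeStack}s (co-registered, equal length).
#' @param propC3,propC4 \linkS4class{AgRaster} pathway fractions.
#' @param params a "VpmParams" bundle.
#' @return GPP stack (gC/m2 per composite).
#' @export
computeGppStack <- function(ndviStack, lswiStack, parStack, tdayStack,
                            propC3, propC4, params = vpmParams()) {
  n <- nLayers(ndviStack)
  stopifnot(nLayers(lswiStack) == n, nLayers(parStack) == n,
            nLayers(tdayStack) == n)
  lswiMax <- rasterValues(computeLswiMax(lswiStack))
  p3 <- rasterValues(propC3); p4 <- rasterValues(propC4)
  layers <- vector("list", n)
  for (i in seq_len(n)) {
    g <- computeGppComposite(rasterValues(getLayer(ndviStack, i)),
                             rasterValues(getLayer(lswiStack, i)),
                             lswiMax,
                             rasterValues(getLayer(parStack, i)),
                             rasterValues(getLayer(tdayStack, i)),
                             p3, p4, params)
    layers[[i]] <- setRasterValues(getLayer(ndviStack, i), g)
  }
  compositeStack(layers, startDates(ndviStack), "GPP", "gC m-2 per composite")
}

#' Seasonal integration of composite GPP
#'
#' Per-pixel sum of the composite GPP layers over the season; pixels where
#' the cropland mask is 0 (or nodata) are set to nodata.
#'
#' @param gppStack a \linkS4class{CompositeStack} of composite GPP.
#' @param mask a co-registered \linkS4class{AgRaster} with 1 = cropland.
#' @return an \linkS4class{AgRaster} of seasonal GPP (gC/m2 per season).
#' @export
integrateSeason <- function(gppStack, mask) {
  stopifnot(is(gppStack, "CompositeStack"), is(mask, "AgRaster"))
  if (!compatibleGrid(getLayer(gppStack, 1L), mask))
    stop("mask is not co-registered with the GPP stack")
  arr <- stackValues(gppStack)
  tot <- apply(arr, c(1L, 2L), sum)   # any nodata composite -> nodata pixel
  m <- rasterValues(mask)
  tot[is.na(m) | m == 0] <- NA_real_
  setRasterValues(mask, tot)
}

#' Composite daily climate series to 16-day model windows
#'
#' For each 16-day window, PAR is accumulated as
#' \eqn{\sum_{days} \bar{PAR}(W/m^2) \times 0.0864} MJ/m2 (0.0864 MJ per
#' W-day), and the daytime mean temperature is the window mean of the daily
#' estimator \eqn{w_1 T_{max} + w_2 T_{min}} (default weights 0.75/0.25,
#' see [vpmParams()]). Windows with any missing day are flagged nodata.
#'
#' @param dates Date vector of the daily series.
#' @param dailyPar daily mean PAR, W/m2.
#' @param dailyTmax,dailyTmin daily max/min 2-m air temperature, degC.
#' @param windowStartDates Date vector of 16-day window starts.
#' @param tdayWeights (Tmax, Tmin) weights of the daytime-mean estimator.
#' @param windowLength days per window (16).
#' @return data.frame with `start`, `par_mj` (MJ/m2 per window) and
#'   `tday_c` (degC); NA rows for incomplete windows.
#' @export
compositeClimate <- function(dates, dailyPar, dailyTmax, dailyTmin,
                             windowStartDates, tdayWeights = c(0.75, 0.25),
                             windowLength = 16L) {
  dates <- as.Date(dates)
  stopifnot(length(dailyPar) == length(dates),
            length(dailyTmax) == length(dates),
            length(dailyTmin) == length(dates),
            length(tdayWeights) == 2L)
  windowStartDates <- as.Date(windowStartDates)
  par_mj <- tday <- rep(NA_real_, length(windowStartDates))
  for (i in seq_along(windowStartDates)) {
    want <- windowStartDates[i] + seq_len(windowLength) - 1L
    idx <- match(want, dates)
    if (anyNA(idx)) next
    p <- dailyPar[idx]; tx <- dailyTmax[idx]; tn <- dailyTmin[idx]
    if (anyNA(p) || anyNA(tx) || anyNA(tn)) next
    par_mj[i] <- sum(p * 0.0864)
    tday[i] <- mean(tdayWeights[1L] * tx + tdayWeights[2L] * tn)
  }
  data.frame(start = windowStartDates, par_mj = par_mj, tday_c = tday)
}

#' Resample a coarse raster onto a target grid
#'
#' Bilinear interpolation (or nearest neighbour) of the coarse field at the
#' target cell centers, as used to bring coarse-grid radiation and
#' temperature onto the model grid. Nodata is preserved: a target cell
#' whose interpolation stencil touches a nodata coarse cell is nodata.
#' Beyond the outermost coarse cell centers values are held at the edge.
#'
#' @param coarse source \linkS4class{AgRaster}.
#' @param target \linkS4class{AgRaster} template defining the output grid.
#' @param method "bilinear" (default) or "nearest".
#' @return an \linkS4class{AgRaster} on the target grid.
#' @export
resampleToGrid <- function(coarse, target, method = c("bilinear", "nearest")) {
  stopifnot(is(coarse, "AgRaster"), is(target, "AgRaster"))
  method <- match.arg(method)
  cd <- dim(coarse@values); td <- dim(target@values)
  tc <- cellCenters(target)
  # coarse must cover the target cell centers (outer cell edges)
  cxmax <- coarse@xmin + cd[2L] * coarse@res
  cymin <- coarse@ymax - cd[1L] * coarse@res
  if (min(tc$lon) < coarse@xmin || max(tc$lon) > cxmax ||
      min(tc$lat) < cymin || max(tc$lat) > coarse@ymax)
    stop("coarse raster does not cover the target extent")
  # fractional (0-based) index of target centers in coarse cell-center space
  fx <- (tc$lon - coarse@xmin) / coarse@res - 0.5
  fy <- (coarse@ymax - tc$lat) / coarse@res - 0.5
  out <- matrix(NA_real_, td[1L], td[2L])
  v <- coarse@values
  if (method == "nearest") {
    ri <- pmin(pmax(round(fy) + 1, 1), cd[1L])
    ci <- pmin(pmax(round(fx) + 1, 1), cd[2L])
    out <- v[cbind(rep(ri, times = td[2L]),
                   rep(ci, each = td[1L]))]
    dim(out) <- td
  } else {
    fx <- pmin(pmax(fx, 0), cd[2L] - 1)
    fy <- pmin(pmax(fy, 0), cd[1L] - 1)
    x0 <- pmin(floor(fx), cd[2L] - 1); y0 <- pmin(floor(fy), cd[1L] - 1)
    wx <- fx - x0; wy <- fy - y0
    # snap weights within float roundoff of a coarse cell center onto it
    eps <- 1e-9
    wx[wx < eps] <- 0
    sx <- wx > 1 - eps
    x0[sx] <- pmin(x0[sx] + 1, cd[2L] - 1); wx[sx] <- 0
    wy[wy < eps] <- 0
    sy <- wy > 1 - eps
    y0[sy] <- pmin(y0[sy] + 1, cd[1L] - 1); wy[sy] <- 0
    # zero-weight neighbours collapse onto the anchor cell so that an
    # exactly-aligned grid round-trips nodata and values identically
    x1 <- ifelse(wx == 0, x0, pmin(x0 + 1, cd[2L] - 1))
    y1 <- ifelse(wy == 0, y0, pmin(y0 + 1, cd[1L] - 1))
    for (r in seq_len(td[1L])) {
      a <- y0[r] + 1L; b <- y1[r] + 1L
      v00 <- v[a, x0 + 1L]; v01 <- v[a, x1 + 1L]
      v10 <- v[b, x0 + 1L]; v11 <- v[b, x1 + 1L]
      out[r, ] <- (1 - wy[r]) * ((1 - wx) * v00 + wx * v01) +
                  wy[r] * ((1 - wx) * v10 + wx * v11)
    }
  }
  agRaster(out, xmin = target@xmin, ymax = target@ymax, res = target@res)
}
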