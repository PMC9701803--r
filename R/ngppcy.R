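#' Crop-combined district yield from statistics
#'
#' The district's combined primary productivity in t/Ha, computed as total
#' production over total area of the considered crops for one season-year.
#'
#' @param records crop-statistics data.frame with `district_id`,
#'   `area_ha`, `production_t`.
#' @return data.frame: `district_id`, `yield_t_per_ha`.
#' @export
districtCombinedYield <- function(records) {
  stopifnot(all(c("district_id", "area_ha", "production_t") %in%
                  names(records)))
  prod <- stats::aggregate(production_t ~ district_id, records, sum)
  area <- stats::aggregate(area_ha ~ district_id, records, sum)
  df <- merge(prod, area, by = "district_id")
  if (any(df$area_ha <= 0)) stop("district with nonpositive crop area")
  data.frame(district_id = df$district_id,
             yield_t_per_ha = df$production_t / df$area_ha)
}

#' Pixel-level normalized yield (NGPPCY)
#'
#' Redistributes district yield statistics to pixels in proportion to each
#' pixel's share of GPP: for pixel p in district d,
#' \deqn{NGPPCY(p) = \frac{GPP(p)}{\overline{GPP}_d} \cdot yield_d}
#' where the district mean is the unweighted mean over the district's
#' cropland (non-nodata GPP) pixels. By construction the unweighted
#' district mean of NGPPCY equals the district yield. Pixels outside
#' cropland are nodata; a district whose mean GPP is zero is set to
#' nodata with a warning.
#'
#' @param seasonalGpp \linkS4class{AgRaster} of seasonal GPP (gC/m2,
#'   nodata off cropland).
#' @param districtLabels co-registered \linkS4class{AgRaster} of district
#'   ids.
#' @param yields data.frame `district_id`, `yield_t_per_ha` covering every
#'   district that has cropland pixels.
#' @return an \linkS4class{AgRaster} of NGPPCY in t/Ha.
#' @export
computeNgppcy <- function(seasonalGpp, districtLabels, yields) {
  stopifnot(is(seasonalGpp, "AgRaster"), is(districtLabels, "AgRaster"),
            all(c("district_id", "yield_t_per_ha") %in% names(yields)))
  if (!compatibleGrid(seasonalGpp, districtLabels))
    stop("rasters are not co-registered")
  g <- rasterValues(seasonalGpp)
  lab <- rasterValues(districtLabels)
  out <- matrix(NA_real_, nrow(g), ncol(g))
  ids <- sort(unique(as.integer(lab[!is.na(lab) & !is.na(g)])))
  missing <- setdiff(ids, yields$district_id)
  if (length(missing))
    stop("missing yield for district(s): ", paste(missing, collapse = ", "))
  for (id in ids) {
    sel <- !is.na(lab) & lab == id & !is.na(g)
    mu <- mean(g[sel])
    if (mu == 0) {
      warning("district ", id, " has zero mean GPP; set to nodata")
      next
    }
    y <- yields$yield_t_per_ha[match(id, yields$district_id)]
    out[sel] <- g[sel] / mu * y
  }
  setRasterValues(seasonalGpp, out)
}
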