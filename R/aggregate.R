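#' District totals of seasonal GPP
#'
#' Zonal aggregation of a seasonal GPP raster over a district-label raster:
#' for each district, the total carbon is the sum over masked cropland
#' pixels of GPP (gC/m2) times the spherical pixel area (m2, cosine-of-
#' latitude scaled). Pixels count towards a district when its label is set,
#' the mask is 1 and the GPP value is not nodata.
#'
#' @param seasonalGpp \linkS4class{AgRaster} of seasonal GPP (gC/m2).
#' @param districtLabels co-registered \linkS4class{AgRaster} of integer
#'   district ids (nodata outside any district).
#' @param mask co-registered \linkS4class{AgRaster}, 1 = cropland.
#' @param season,year labels copied into the output.
#' @return data.frame: `district_id`, `season`, `year`, `sat_gpp_total_gC`,
#'   `cropland_area_ha`, `n_pixels` (one row per district id present).
#' @export
aggregateDistricts <- function(seasonalGpp, districtLabels, mask,
                               season = NA_character_, year = NA_integer_) {
  stopifnot(is(seasonalGpp, "AgRaster"), is(districtLabels, "AgRaster"),
            is(mask, "AgRaster"))
  if (!compatibleGrid(seasonalGpp, districtLabels) ||
      !compatibleGrid(seasonalGpp, mask))
    stop("rasters are not co-registered")
  lab <- rasterValues(districtLabels)
  if (all(is.na(lab))) stop("district label raster is empty")
  g <- rasterValues(seasonalGpp)
  m <- rasterValues(mask)
  area <- matrix(pixelAreaM2(cellCenters(seasonalGpp)$lat,
                             cellSize(seasonalGpp)),
                 nrow = nrow(g), ncol = ncol(g))
  use <- !is.na(lab) & !is.na(m) & m == 1 & !is.na(g)
  ids <- sort(unique(as.integer(lab[!is.na(lab)])))
  res <- lapply(ids, function(id) {
    sel <- use & lab == id
    data.frame(district_id = id, season = season, year = year,
               sat_gpp_total_gC = sum(g[sel] * area[sel]),
               cropland_area_ha = sum(area[sel]) / 1e4,
               n_pixels = sum(sel))
  })
  do.call(rbind, res)
}

#' District retention filters
#'
#' Districts comparable with crop statistics must have at least
#' `minAreaHa` of total cropped area (75,000 Ha default) and the modelled
#' ("considered") crops must cover at least `minShare` (30% default) of
#' that total. Returns every district with its retention decision and, for
#' excluded districts, the reason(s).
#'
#' @param records crop-statistics data.frame with `district_id` and
#'   `area_ha` for the considered crops (rows are district x crop).
#' @param totalAreaHa optional data.frame `district_id`, `total_area_ha`
#'   with the district's total cropped area; when NULL the considered
#'   crops are taken to be the whole cropped area (share 1).
#' @param minAreaHa minimum total cropped area, Ha.
#' @param minShare minimum considered-crop share of total cropped area.
#' @return data.frame: `district_id`, `total_area_ha`, `considered_share`,
#'   `retained`, `exclusion_reason` ("" when retained).
#' @export
filterDistricts <- function(records, totalAreaHa = NULL,
                            minAreaHa = 75000, minShare = 0.30) {
  stopifnot(all(c("district_id", "area_ha") %in% names(records)))
  if (any(records$area_ha < 0, na.rm = TRUE)) stop("negative crop areas")
  considered <- stats::aggregate(area_ha ~ district_id, records, sum)
  names(considered)[2L] <- "considered_area_ha"
  if (is.null(totalAreaHa)) {
    totalAreaHa <- data.frame(district_id = considered$district_id,
                              total_area_ha = considered$considered_area_ha)
  }
  stopifnot(all(c("district_id", "total_area_ha") %in% names(totalAreaHa)))
  if (any(totalAreaHa$total_area_ha < 0, na.rm = TRUE))
    stop("negative total areas")
  df <- merge(totalAreaHa, considered, by = "district_id", all.x = TRUE)
  df$considered_area_ha[is.na(df$considered_area_ha)] <- 0
  df$considered_share <- ifelse(df$total_area_ha > 0,
                                df$considered_area_ha / df$total_area_ha, 0)
  smallArea <- df$total_area_ha < minAreaHa
  smallShare <- df$considered_share < minShare
  df$retained <- !smallArea & !smallShare
  df$exclusion_reason <- ""
  df$exclusion_reason[smallArea] <- sprintf("area < %g Ha", minAreaHa)
  df$exclusion_reason[smallShare] <- paste0(
    df$exclusion_reason[smallShare],
    ifelse(nzchar(df$exclusion_reason[smallShare]), "; ", ""),
    sprintf("considered share < %g", minShare))
  df <- df[order(df$district_id),
           c("district_id", "total_area_ha", "considered_share",
             "retained", "exclusion_reason")]
  rownames(df) <- NULL
  df
}
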