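# run expr under a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Synthetic-scene configuration
#'
#' Defines the grid, season, composite count, climate downscaling and
#' noise levels of a synthetic agricultural scene. The defaults describe
#' the package's reference desk-scale scene: a 20 x 20 grid of 0.005
#' degree (~500 m) cells, 6 districts, one monsoon season of 8 16-day
#' composites, climate generated on a 4x coarser grid, 2% NDVI noise and
#' 5% production noise.
#'
#' @param gridRows,gridCols grid dimensions (>= 2 each).
#' @param cellSizeDeg cell size, degrees.
#' @param originLon,originLat western / northern grid edges, degrees.
#' @param nDistricts number of districts (<= gridRows * gridCols).
#' @param season "monsoon" (Jun-Oct) or "winter" (Nov-Mar, labeled by its
#'   starting year).
#' @param year calendar year of the season start.
#' @param nComposites number of 16-day composites in the season.
#' @param climateDownscaleFactor integer >= 1; climate is generated on a
#'   grid this many times coarser, then resampled.
#' @param noiseSdNdvi additive NDVI noise SD (>= 0).
#' @param noiseSdProduction multiplicative lognormal production noise SD
#'   (>= 0).
#' @param rngSeed integer seed making the scene reproducible.
#' @return list of class "SceneConfig".
#' @export
sceneConfig <- function(gridRows = 20L, gridCols = 20L, cellSizeDeg = 0.005,
                        originLon = 75, originLat = 22, nDistricts = 6L,
                        season = c("monsoon", "winter"), year = 2001L,
                        nComposites = 8L, climateDownscaleFactor = 4L,
                        noiseSdNdvi = 0.02, noiseSdProduction = 0.05,
                        rngSeed = 1L) {
  season <- match.arg(season)
  cfg <- list(gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
              cellSizeDeg = cellSizeDeg, originLon = originLon,
              originLat = originLat, nDistricts = as.integer(nDistricts),
              season = season, year = as.integer(year),
              nComposites = as.integer(nComposites),
              climateDownscaleFactor = as.integer(climateDownscaleFactor),
              noiseSdNdvi = noiseSdNdvi,
              noiseSdProduction = noiseSdProduction,
              rngSeed = as.integer(rngSeed))
  if (cfg$gridRows < 2L || cfg$gridCols < 2L)
    stop("grid must be at least 2 x 2")
  if (cfg$nDistricts < 1L || cfg$nDistricts > cfg$gridRows * cfg$gridCols)
    stop("nDistricts must be in [1, gridRows * gridCols]")
  if (cfg$nComposites < 1L) stop("need at least one composite")
  if (cfg$climateDownscaleFactor < 1L) stop("downscale factor must be >= 1")
  if (cfg$noiseSdNdvi < 0 || cfg$noiseSdProduction < 0)
    stop("noise SDs must be nonnegative")
  structure(cfg, class = "SceneConfig")
}

#' First 16-day window start of a season
#' @param season "monsoon" or "winter".
#' @param year season start year.
#' @return a Date (Jun 1 for monsoon, Nov 1 for winter).
#' @export
seasonStartDate <- function(season, year) {
  as.Date(sprintf("%d-%s-01", year,
                  if (season == "monsoon") "06" else "11"))
}

# rectangular block partition of the grid into n district labels
.districtBlocks <- function(nrows, ncols, n) {
  nbr <- max(1L, floor(sqrt(n)))
  nbc <- ceiling(n / nbr)
  rb <- ceiling(seq_len(nrows) / nrows * nbr)
  cb <- ceiling(seq_len(ncols) / ncols * nbc)
  lab <- outer(rb, cb, function(r, c) (r - 1L) * nbc + c)
  lab[lab > n] <- n
  lab
}

#' Generate a self-consistent synthetic agricultural scene
#'
#' Emulates the inputs of the seasonal cropland GPP pipeline with known
#' ground truth: smooth unimodal (beta-pulse) NDVI trajectories on
#' cropland with per-district phenology jitter and low flat NDVI off
#' cropland; LSWI as an NDVI-correlated field; daily PAR and min/max
#' temperature series generated on a coarser climate grid, composited to
#' 16-day windows and bilinearly resampled to the model grid; smooth
#' C3/C4 fraction fields summing to 1; a cropland mask; and a rectangular
#' block district partition. The true seasonal GPP is obtained by running
#' the VPM forward on the noise-free drivers, so every downstream stage
#' can be checked against it.
#'
#' @param config a "SceneConfig", see [sceneConfig()].
#' @param params a "VpmParams" bundle used for the forward truth run.
#' @return list of class "SyntheticScene": driver stacks (`ndviStack`,
#'   `lswiStack`, `parStack`, `tdayStack`), rasters `propC3`, `propC4`,
#'   `croplandMask`, `districtLabels`, the `config`, and `truth` (class
#'   "SceneTruth") holding `trueSeasonalGpp` and the `districtGpp` totals
#'   table.
#' @export
generateScene <- function(config, params = vpmParams()) {
  stopifnot(inherits(config, "SceneConfig"))
  withSeed(config$rngSeed, {
    nr <- config$gridRows; nc <- config$gridCols
    template <- agRaster(matrix(NA_real_, nr, nc), xmin = config$originLon,
                         ymax = config$originLat, res = config$cellSizeDeg)
    lab <- .districtBlocks(nr, nc, config$nDistricts)

    maskM <- matrix(as.numeric(stats::runif(nr * nc) < 0.88), nr, nc)
    for (d in seq_len(config$nDistricts)) {    # every district gets cropland
      sel <- which(lab == d)
      if (sum(maskM[sel]) < 3) maskM[sel[seq_len(min(3L, length(sel)))]] <- 1
    }

    # per-district phenology jitter, per-pixel amplitude variation
    peakPos <- stats::runif(config$nDistricts, 0.40, 0.60)
    peakHeight <- stats::runif(config$nDistricts, 0.65, 0.85)
    ampPix <- matrix(stats::runif(nr * nc, 0.90, 1.10), nr, nc)

    k <- 6
    xs <- (seq_len(config$nComposites) - 0.5) / config$nComposites
    ndviTrue <- vector("list", config$nComposites)
    for (i in seq_len(config$nComposites)) {
      m <- matrix(0.12, nr, nc)
      for (d in seq_len(config$nDistricts)) {
        a <- 1 + peakPos[d] * k; b <- 1 + (1 - peakPos[d]) * k
        mode <- (a - 1) / (a + b - 2)
        pulse <- stats::dbeta(xs[i], a, b) / stats::dbeta(mode, a, b)
        sel <- lab == d & maskM == 1
        m[sel] <- 0.15 + (peakHeight[d] - 0.15) * pulse * ampPix[sel]
      }
      ndviTrue[[i]] <- pmin(pmax(m, -1), 1)
    }
    lswiTrue <- lapply(ndviTrue, function(m) pmin(pmax(0.75 * m - 0.18, -1), 1))

    dates <- seasonStartDate(config$season, config$year) +
      (seq_len(config$nComposites) - 1L) * 16L

    # daily climate on the coarse grid, composited then resampled
    f <- config$climateDownscaleFactor
    nrC <- ceiling(nr / f); ncC <- ceiling(nc / f)
    resC <- config$cellSizeDeg * f
    dayDates <- dates[1L] + seq_len(config$nComposites * 16L) - 1L
    frac <- (seq_along(dayDates) - 0.5) / length(dayDates)
    parW <- tdayW <- array(NA_real_, c(nrC, ncC, config$nComposites))
    for (r in seq_len(nrC)) for (c2 in seq_len(ncC)) {
      gy <- (r - 0.5) / nrC; gx <- (c2 - 0.5) / ncC
      dailyPar <- (180 + 50 * (1 - gy) + 10 * gx) *
        (0.9 + 0.2 * sin(pi * frac))
      tmax <- 30 + 4 * (1 - gy) + 3 * sin(pi * frac)
      tmin <- tmax - (8 + 2 * gx)
      cc <- compositeClimate(dayDates, dailyPar, tmax, tmin, dates,
                             tdayWeights = params$tdayWeights)
      parW[r, c2, ] <- cc$par_mj
      tdayW[r, c2, ] <- cc$tday_c
    }
    coarse <- function(m) agRaster(m, xmin = config$originLon,
                                   ymax = config$originLat, res = resC)
    parLayers <- tdayLayers <- vector("list", config$nComposites)
    for (i in seq_len(config$nComposites)) {
      parLayers[[i]] <- resampleToGrid(coarse(parW[, , i]), template)
      tdayLayers[[i]] <- resampleToGrid(coarse(tdayW[, , i]), template)
    }

    # smooth C3/C4 partition, clipped away from the extremes
    rg <- matrix(rep((seq_len(nr) - 0.5) / nr, nc), nr, nc)
    cg <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
    propC4m <- pmin(pmax(0.30 + 0.20 * sin(2 * pi * cg) * cos(pi * rg), 0), 0.8)
    propC3m <- 1 - propC4m

    asRaster <- function(m) setRasterValues(template, m)
    mkStack <- function(ms, name, units)
      compositeStack(lapply(ms, asRaster), dates, name, units)

    noisy <- function(m, sd) if (sd > 0)
      pmin(pmax(m + matrix(stats::rnorm(nr * nc, 0, sd), nr, nc), -1), 1)
      else m
    ndviEm <- lapply(ndviTrue, noisy, sd = config$noiseSdNdvi)
    lswiEm <- lapply(lswiTrue, noisy, sd = 0.5 * config$noiseSdNdvi)

    ndviStack <- mkStack(ndviEm, "NDVI", "")
    lswiStack <- mkStack(lswiEm, "LSWI", "")
    parStack <- compositeStack(parLayers, dates, "PAR", "MJ m-2 per composite")
    tdayStack <- compositeStack(tdayLayers, dates, "Tday", "degC")
    propC3 <- asRaster(propC3m); propC4 <- asRaster(propC4m)
    maskR <- asRaster(maskM)
    labR <- asRaster(lab)

    gppTrueStack <- computeGppStack(mkStack(ndviTrue, "NDVI", ""),
                                    mkStack(lswiTrue, "LSWI", ""),
                                    parStack, tdayStack, propC3, propC4,
                                    params)
    trueGpp <- integrateSeason(gppTrueStack, maskR)
    districtGpp <- aggregateDistricts(trueGpp, labR, maskR,
                                      season = config$season,
                                      year = config$year)

    structure(list(
      ndviStack = ndviStack, lswiStack = lswiStack, parStack = parStack,
      tdayStack = tdayStack, propC3 = propC3, propC4 = propC4,
      croplandMask = maskR, districtLabels = labR, config = config,
      truth = structure(list(trueSeasonalGpp = trueGpp,
                             districtGpp = districtGpp),
                        class = "SceneTruth")),
      class = "SyntheticScene")
  })
}

#' Generate district crop-production statistics from a scene
#'
#' Inverts the statistics-to-GPP relation against the scene's true
#' district GPP totals: each district's satellite GPP is partitioned
#' across crops by Dirichlet-drawn (or supplied) shares and converted to
#' production as
#' \deqn{PROD_i = share_i \cdot Sat.GPP_D \cdot
#'   \frac{HI_i}{1.15 (1 + RC_i)(1 - MC_i)}}
#' (grams to tonnes), after which multiplicative lognormal noise of the
#' given SD is applied. The true harvest indices are drawn on the
#' shared-s family (one scalar applied to every free crop's bounds) so
#' that the single district GPP equation identifies them exactly; crops
#' with a fixed harvest index use it as truth.
#'
#' @param scene a "SyntheticScene" from [generateScene()].
#' @param crops crop names to generate (must be in `coefficients`).
#' @param coefficients a "CropCoefficients" table.
#' @param productionNoiseSd lognormal sdlog of the production noise.
#' @param sTrue optional shared bound-fraction in (0, 1) defining the true
#'   harvest indices; drawn uniformly in (0.2, 0.8) when NULL.
#' @param shares optional nDistricts x nCrops share matrix (rows sum to
#'   1); Dirichlet(3) draws when NULL.
#' @param litterFactor,carbonFraction conversion constants, see
#'   [productionToGpp()].
#' @param seed RNG seed for shares, truth draw and noise.
#' @return list: `records` (data.frame `district_id`, `year`, `season`,
#'   `crop`, `area_ha`, `production_t`), `trueHi` (named per crop),
#'   `sTrue`, `shares`.
#' @export
generateCropStats <- function(scene, crops = c("rice", "wheat", "maize"),
                              coefficients = defaultCropCoefficients(),
                              productionNoiseSd = 0, sTrue = NULL,
                              shares = NULL, litterFactor = 1.15,
                              carbonFraction = 1,
                              seed = scene$config$rngSeed) {
  stopifnot(inherits(scene, "SyntheticScene"), productionNoiseSd >= 0)
  cf <- .coefRow(coefficients, crops)
  if (any(!is.na(cf$fixed_hi) & cf$fixed_hi <= 0))
    stop("fixed harvest index must be positive")
  if (any(cf$mc >= 1)) stop("moisture content must be < 1")
  dg <- scene$truth$districtGpp
  withSeed(seed, {
    if (is.null(sTrue)) sTrue <- stats::runif(1L, 0.2, 0.8)
    stopifnot(sTrue > 0, sTrue < 1)
    trueHi <- cf$hi_lower + sTrue * (cf$hi_upper - cf$hi_lower)
    trueHi[!is.na(cf$fixed_hi)] <- cf$fixed_hi[!is.na(cf$fixed_hi)]
    names(trueHi) <- crops
    nd <- nrow(dg); nc <- length(crops)
    if (is.null(shares)) {
      g <- matrix(stats::rgamma(nd * nc, shape = 3), nd, nc)
      shares <- g / rowSums(g)
    }
    stopifnot(nrow(shares) == nd, ncol(shares) == nc,
              all(abs(rowSums(shares) - 1) < 1e-9))
    recs <- vector("list", nd)
    for (i in seq_len(nd)) {
      gppShare <- shares[i, ] * dg$sat_gpp_total_gC[i]
      prod_t <- gppShare * trueHi /
        (litterFactor * carbonFraction * (1 + cf$rc) * (1 - cf$mc)) / 1e6
      if (productionNoiseSd > 0)
        prod_t <- prod_t * exp(stats::rnorm(nc, 0, productionNoiseSd))
      recs[[i]] <- data.frame(district_id = dg$district_id[i],
                              year = scene$config$year,
                              season = scene$config$season,
                              crop = crops,
                              area_ha = shares[i, ] * dg$cropland_area_ha[i],
                              production_t = prod_t)
    }
    list(records = do.call(rbind, recs), trueHi = trueHi, sTrue = sTrue,
         shares = shares)
  })
}
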