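#' End-to-end pipeline configuration
#'
#' Bundles the scene definition, crop list, coefficient table, district
#' filter thresholds and solver choice for [runPipeline()]. The filter
#' defaults are the operational thresholds (75,000 Ha and 30% considered
#' share); desk-scale synthetic scenes cover far less area than a real
#' district, so toy runs pass a `minAreaHa` scaled to the scene (see the
#' package vignette).
#'
#' @param scene a "SceneConfig".
#' @param crops crop names to simulate and calibrate.
#' @param coefficients a "CropCoefficients" table.
#' @param minAreaHa,minShare district retention thresholds, see
#'   [filterDistricts()].
#' @param solver "bisection" or "optim", see [calibrateHi()].
#' @param litterFactor,carbonFraction see [productionToGpp()].
#' @param params a "VpmParams" bundle.
#' @return list of class "PipelineConfig".
#' @export
pipelineConfig <- function(scene = sceneConfig(),
                           crops = c("rice", "wheat", "maize"),
                           coefficients = defaultCropCoefficients(),
                           minAreaHa = 75000, minShare = 0.30,
                           solver = c("bisection", "optim"),
                           litterFactor = 1.15, carbonFraction = 1,
                           params = vpmParams()) {
  stopifnot(inherits(scene, "SceneConfig"), minAreaHa >= 0, minShare >= 0)
  solver <- match.arg(solver)
  .coefRow(coefficients, crops)   # pre-flight: every crop has coefficients
  structure(list(scene = scene, crops = crops, coefficients = coefficients,
                 minAreaHa = minAreaHa, minShare = minShare, solver = solver,
                 litterFactor = litterFactor,
                 carbonFraction = carbonFraction, params = params),
            class = "PipelineConfig")
}

# deterministic CSV writer: snake_case columns, 9 significant digits
writeCsvArtifact <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.9g", df[[j]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full seasonal GPP pipeline on a synthetic scene pair
#'
#' Executes simulate -> GPP -> aggregate -> filter -> calibrate ->
#' validate -> normalize: generates a calibration-year scene and a
#' following validation-year scene (same true harvest indices, new
#' weather and noise draws), runs the VPM forward on the emitted driver
#' stacks, aggregates seasonal GPP to districts, applies the retention
#' filters, calibrates harvest indices against the calibration-year
#' statistics, validates them against the next year, and produces the
#' NGPPCY normalized-yield raster. All artifacts are written to `outdir`
#' together with a manifest recording the seed and a config hash; a rerun
#' with the same config and seed reproduces every CSV/JSON byte for byte.
#'
#' @param config a "PipelineConfig".
#' @param outdir output directory (created if needed).
#' @param seed integer master seed; the scene and statistics seeds are
#'   derived from it.
#' @return (invisibly) list with `calib`, `validation`, `metrics`,
#'   `districtGpp`, `filters`, `ngppcy`, `seasonalGpp`, `files`.
#' @export
runPipeline <- function(config, outdir, seed = config$scene$rngSeed) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(s) message(sprintf("[%6.2fs] %s",
                                       proc.time()[["elapsed"]] - t0, s))

  # simulate: calibration year and the following validation year
  stage("simulate")
  cfg1 <- config$scene; cfg1$rngSeed <- as.integer(seed)
  cfg2 <- cfg1; cfg2$year <- cfg1$year + 1L
  cfg2$rngSeed <- as.integer(seed + 1000L)
  scene1 <- generateScene(cfg1, config$params)
  scene2 <- generateScene(cfg2, config$params)
  sTrue <- withSeed(seed, stats::runif(1L, 0.2, 0.8))
  stats1 <- generateCropStats(scene1, config$crops, config$coefficients,
                              productionNoiseSd = cfg1$noiseSdProduction,
                              sTrue = sTrue, seed = seed + 1L,
                              litterFactor = config$litterFactor,
                              carbonFraction = config$carbonFraction)
  stats2 <- generateCropStats(scene2, config$crops, config$coefficients,
                              productionNoiseSd = cfg1$noiseSdProduction,
                              sTrue = sTrue, seed = seed + 2L,
                              litterFactor = config$litterFactor,
                              carbonFraction = config$carbonFraction)

  # forward GPP on the emitted (noisy) drivers
  stage("gpp")
  seasonal <- list()
  for (s in list(scene1, scene2)) {
    g <- computeGppStack(s$ndviStack, s$lswiStack, s$parStack, s$tdayStack,
                         s$propC3, s$propC4, config$params)
    seasonal[[as.character(s$config$year)]] <-
      integrateSeason(g, s$croplandMask)
  }

  stage("aggregate")
  dg1 <- aggregateDistricts(seasonal[[1L]], scene1$districtLabels,
                            scene1$croplandMask, cfg1$season, cfg1$year)
  dg2 <- aggregateDistricts(seasonal[[2L]], scene2$districtLabels,
                            scene2$croplandMask, cfg2$season, cfg2$year)

  stage("filter")
  filt <- filterDistricts(stats1$records, minAreaHa = config$minAreaHa,
                          minShare = config$minShare)
  retained <- filt$district_id[filt$retained]
  if (length(retained) == 0L) stop("filter: no districts retained")

  stage("calibrate")
  calib <- calibrateDistricts(dg1[dg1$district_id %in% retained, ],
                              stats1$records, config$coefficients,
                              method = config$solver,
                              litterFactor = config$litterFactor,
                              carbonFraction = config$carbonFraction)
  calibPairs <- unique(calib[, c("district_id", "sat_gpp_gC", "stat_gpp_gC")])

  stage("validate")
  valPairs <- validateNextYear(calib, stats2$records,
                               dg2[dg2$district_id %in% retained, ],
                               config$coefficients,
                               litterFactor = config$litterFactor,
                               carbonFraction = config$carbonFraction)

  metrics <- list(
    calibration = list(r2 = computeR2(calibPairs),
                       nrmse_pct = computeNrmse(calibPairs),
                       n_districts = nrow(calibPairs),
                       season = cfg1$season, year = cfg1$year),
    validation = list(r2 = computeR2(valPairs),
                      nrmse_pct = computeNrmse(valPairs),
                      n_districts = nrow(valPairs),
                      season = cfg2$season, year = cfg2$year))

  stage("normalize")
  yields <- districtCombinedYield(stats1$records)
  ngppcy <- computeNgppcy(seasonal[[1L]], scene1$districtLabels, yields)

  stage("write")
  tag <- function(cfg) sprintf("%s%d", toupper(substr(cfg$season, 1L, 1L)),
                               cfg$year)
  files <- c(
    seasonal_gpp = writeRaster(seasonal[[1L]],
      file.path(outdir, sprintf("seasonal_gpp_%s.asc", tag(cfg1)))),
    ngppcy = writeRaster(ngppcy,
      file.path(outdir, sprintf("NGPPCY-%s.asc", tag(cfg1)))),
    districts = writeCsvArtifact(rbind(dg1, dg2),
      file.path(outdir, "districts.csv")),
    filters = writeCsvArtifact(filt, file.path(outdir, "district_filters.csv")),
    crop_stats = writeCsvArtifact(rbind(stats1$records, stats2$records),
      file.path(outdir, "crop_stats.csv")),
    calibration = writeCsvArtifact(calib, file.path(outdir, "calibration.csv")),
    validation = writeCsvArtifact(valPairs,
      file.path(outdir, "validation.csv")))
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  files["metrics"] <- file.path(outdir, "metrics.json")

  cfgPath <- file.path(outdir, "config.json")
  cfgJson <- list(scene = unclass(cfg1), crops = config$crops,
                  coefficients = as.data.frame(unclass(config$coefficients)),
                  minAreaHa = config$minAreaHa, minShare = config$minShare,
                  solver = config$solver, litterFactor = config$litterFactor,
                  carbonFraction = config$carbonFraction)
  jsonlite::write_json(cfgJson, cfgPath, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  manifest <- list(seed = as.integer(seed),
                   config_md5 = unname(tools::md5sum(cfgPath)),
                   files = basename(unname(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  stage("done")
  invisible(list(calib = calib, validation = valPairs, metrics = metrics,
                 districtGpp = rbind(dg1, dg2), filters = filt,
                 ngppcy = ngppcy, seasonalGpp = seasonal[[1L]],
                 trueHi = stats1$trueHi, files = files))
}

#' Read a pipeline configuration from YAML
#'
#' Maps a YAML file with optional `scene`, `crops`, `coefficients`,
#' `filters` and `solver` sections onto [pipelineConfig()]; omitted
#' entries keep the package defaults.
#'
#' @param path YAML file path.
#' @return a "PipelineConfig".
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  y <- yaml::read_yaml(path)
  scene <- do.call(sceneConfig, y$scene %||% list())
  coef <- if (is.null(y$coefficients)) defaultCropCoefficients()
          else do.call(cropCoefficients, y$coefficients)
  pipelineConfig(scene = scene,
                 crops = y$crops %||% c("rice", "wheat", "maize"),
                 coefficients = coef,
                 minAreaHa = y$filters$min_area_ha %||% 75000,
                 minShare = y$filters$min_share %||% 0.30,
                 solver = y$solver %||% "bisection",
                 litterFactor = y$litter_factor %||% 1.15,
                 carbonFraction = y$carbon_fraction %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
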