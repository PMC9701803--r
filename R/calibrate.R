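#' Per-crop coefficient table
#'
#' Harvest-index bounds, respiration coefficient (RC, applied as 1 + RC)
#' and moisture content (MC, removed as 1 - MC) for each crop. Crops with
#' a `fixed_hi` (sugarcane: 0.69) are excluded from optimization and their
#' harvest index held constant.
#'
#' @param crop character crop names.
#' @param hi_lower,hi_upper harvest-index bounds, 0 < lower <= upper < 1.
#' @param rc respiration coefficients (>= 0).
#' @param mc moisture contents in [0, 1).
#' @param fixed_hi optional fixed harvest index per crop (NA = free).
#' @return data.frame of class "CropCoefficients".
#' @export
cropCoefficients <- function(crop, hi_lower, hi_upper, rc, mc,
                             fixed_hi = NA_real_) {
  df <- data.frame(crop = as.character(crop), hi_lower = hi_lower,
                   hi_upper = hi_upper, rc = rc, mc = mc,
                   fixed_hi = fixed_hi)
  if (anyDuplicated(df$crop)) stop("duplicate crop names")
  with(df, {
    if (any(!(hi_lower > 0 & hi_lower <= hi_upper & hi_upper < 1)))
      stop("need 0 < hi_lower <= hi_upper < 1")
    if (any(mc < 0 | mc >= 1)) stop("need 0 <= mc < 1")
    if (any(rc < 0)) stop("need rc >= 0")
  })
  class(df) <- c("CropCoefficients", "data.frame")
  df
}

#' Default crop coefficient table
#'
#' Representative literature-style constants for the crops the synthetic
#' scenes use; harvest-index bounds bracket typical field values, the
#' sugarcane harvest index is fixed at 0.69.
#'
#' @return a "CropCoefficients" data.frame.
#' @export
defaultCropCoefficients <- function() {
  cropCoefficients(
    crop     = c("rice", "wheat", "maize", "pulses", "sugarcane"),
    hi_lower = c(0.15, 0.20, 0.20, 0.10, 0.60),
    hi_upper = c(0.55, 0.55, 0.60, 0.40, 0.80),
    rc       = c(0.45, 0.40, 0.45, 0.50, 0.30),
    mc       = c(0.14, 0.12, 0.15, 0.10, 0.70),
    fixed_hi = c(NA, NA, NA, NA, 0.69))
}

.coefRow <- function(coefficients, crop) {
  i <- match(crop, coefficients$crop)
  if (anyNA(i)) stop("missing coefficients for crop(s): ",
                     paste(crop[is.na(i)], collapse = ", "))
  coefficients[i, , drop = FALSE]
}

.fillFixedHi <- function(hi, records, coefficients) {
  cf <- .coefRow(coefficients, records$crop)
  fixed <- !is.na(cf$fixed_hi)
  if (is.null(hi)) hi <- numeric(0)
  out <- hi[records$crop]
  out[fixed] <- cf$fixed_hi[fixed]
  if (anyNA(out)) stop("no harvest index supplied for crop(s): ",
                       paste(records$crop[is.na(out)], collapse = ", "))
  names(out) <- records$crop
  out
}

#' Convert crop production statistics to GPP
#'
#' Statistics-derived gross primary productivity of one district-season:
#' \deqn{GPP_{stat} = 1.15 \sum_i \frac{PROD_i}{HI_i} (1 + RC_i)(1 - MC_i)}
#' with production in tonnes converted to grams (1 t = 1e6 g). The 1.15
#' multiplier accounts for litterfall and energy-efficiency losses not
#' captured by above-ground biomass. `carbonFraction` (default 1) is an
#' optional biomass-to-carbon conversion applied on top.
#'
#' @param records data.frame rows of one district-season: `crop`,
#'   `production_t` (tonnes); `area_ha` may be present and is ignored.
#' @param coefficients a "CropCoefficients" table covering every crop.
#' @param hi named numeric of harvest indices per crop; crops with a
#'   `fixed_hi` in `coefficients` may be omitted (the fixed value is used).
#' @param litterFactor litterfall/energy-efficiency multiplier (1.15).
#' @param carbonFraction biomass-to-carbon factor (1).
#' @return statistics-derived GPP in grams of carbon (scalar).
#' @export
productionToGpp <- function(records, coefficients, hi = numeric(0),
                            litterFactor = 1.15, carbonFraction = 1) {
  stopifnot(all(c("crop", "production_t") %in% names(records)))
  if (nrow(records) == 0L) return(0)
  if (any(records$production_t < 0)) stop("negative production")
  hiUse <- .fillFixedHi(hi, records, coefficients)
  if (any(hiUse <= 0 | hiUse >= 1)) stop("harvest indices must lie in (0, 1)")
  cf <- .coefRow(coefficients, records$crop)
  if (any(cf$mc >= 1)) stop("moisture content must be < 1")
  litterFactor * carbonFraction *
    sum(records$production_t * 1e6 / hiUse * (1 + cf$rc) * (1 - cf$mc))
}

# statistics GPP along the shared-s family hi_i(s) = lower_i + s (upper_i -
# lower_i); strictly decreasing in s because each term is PROD_i / hi_i
.statGppAtS <- function(s, records, cf, coefficients, litterFactor,
                        carbonFraction) {
  hi <- cf$hi_lower + s * (cf$hi_upper - cf$hi_lower)
  hi[!is.na(cf$fixed_hi)] <- cf$fixed_hi[!is.na(cf$fixed_hi)]
  names(hi) <- cf$crop
  productionToGpp(records, coefficients, hi, litterFactor, carbonFraction)
}

#' Calibrate district harvest indices against satellite GPP
#'
#' Finds the harvest-index vector, within per-crop bounds, that minimizes
#' \eqn{Z = |Sat.GPP_D - GPP_{stat}(HI)|} for one district-season-year.
#' Crops with a fixed harvest index are held constant.
#'
#' The default solver parametrizes every free harvest index as
#' \eqn{HI_i = lower_i + s (upper_i - lower_i)} with one shared
#' \eqn{s \in [0, 1]}: the objective is strictly monotone in s, so a
#' bisection to 1e-10 on s finds the unique interior zero, falling back to
#' the nearer bound when no interior zero exists (the single district
#' equation cannot identify several independent harvest indices). The
#' `"optim"` backend instead runs a multivariate bounded quasi-Newton
#' minimizer (L-BFGS-B) on all free harvest indices from the bound
#' midpoints.
#'
#' @param satGpp satellite seasonal district GPP total, grams carbon.
#' @param records crop-statistics rows of this district-season (`crop`,
#'   `production_t`).
#' @param coefficients a "CropCoefficients" table.
#' @param method "bisection" (shared-s, default) or "optim".
#' @param litterFactor,carbonFraction see [productionToGpp()].
#' @param tol bisection tolerance on s.
#' @return list of class "CalibrationResult": `hi` (named, all crops),
#'   `s` (shared parameter, NA for "optim"), `residual_z` (grams),
#'   `at_bound` (named logical over free crops), `objective_evals`,
#'   `stat_gpp` at the optimum.
#' @export
calibrateHi <- function(satGpp, records, coefficients,
                        method = c("bisection", "optim"),
                        litterFactor = 1.15, carbonFraction = 1,
                        tol = 1e-10) {
  method <- match.arg(method)
  if (nrow(records) == 0L) stop("no crop records for this district")
  stopifnot(is.finite(satGpp), satGpp >= 0)
  cf <- .coefRow(coefficients, records$crop)
  free <- is.na(cf$fixed_hi)
  if (!any(free)) stop("need at least one crop with a free harvest index")
  evals <- 0L
  f <- function(s) {
    evals <<- evals + 1L
    .statGppAtS(s, records, cf, coefficients, litterFactor, carbonFraction)
  }
  gMid <- abs(satGpp - f(0.5))   # midpoint-start reference objective

  if (method == "bisection") {
    g0 <- f(0); g1 <- f(1)       # g0 = largest achievable stat GPP
    if (satGpp >= g0) {
      s <- 0
    } else if (satGpp <= g1) {
      s <- 1
    } else {
      lo <- 0; hi <- 1
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (f(mid) > satGpp) lo <- mid else hi <- mid
      }
      s <- (lo + hi) / 2
      # secant polish of the bracketed root (f is smooth and monotone)
      flo <- f(lo) - satGpp; fhi <- f(hi) - satGpp
      for (it in 1:4) {
        if (fhi == flo) break
        sn <- hi - fhi * (hi - lo) / (fhi - flo)
        if (!is.finite(sn) || sn < 0 || sn > 1) break
        fn <- f(sn) - satGpp
        lo <- hi; flo <- fhi; hi <- sn; fhi <- fn
        if (fn == 0) break
      }
      if (abs(fhi) < abs(f(s) - satGpp)) s <- hi
    }
    hiVec <- cf$hi_lower + s * (cf$hi_upper - cf$hi_lower)
    sHat <- s
  } else {
    par0 <- (cf$hi_lower[free] + cf$hi_upper[free]) / 2
    obj <- function(p) {
      hi <- cf$hi_lower
      hi[free] <- p
      names(hi) <- cf$crop
      ((satGpp - productionToGpp(records, coefficients, hi, litterFactor,
                                 carbonFraction)) / max(satGpp, 1))^2
    }
    scale <- max(satGpp, 1)
    cfree <- litterFactor * carbonFraction * records$production_t[free] *
      1e6 * (1 + cf$rc[free]) * (1 - cf$mc[free])
    grad <- function(p) {
      hi <- cf$hi_lower
      hi[free] <- p
      names(hi) <- cf$crop
      r <- (satGpp - productionToGpp(records, coefficients, hi, litterFactor,
                                     carbonFraction)) / scale
      2 * r * (cfree / p^2) / scale
    }
    fit <- stats::optim(par0, obj, gr = grad, method = "L-BFGS-B",
                        lower = cf$hi_lower[free], upper = cf$hi_upper[free],
                        control = list(factr = 10, pgtol = 1e-14,
                                       maxit = 500))
    evals <- evals + fit$counts[["function"]]
    hiVec <- cf$hi_lower
    hiVec[free] <- fit$par
    sHat <- NA_real_
  }
  hiVec[!free] <- cf$fixed_hi[!free]
  names(hiVec) <- cf$crop
  statHat <- productionToGpp(records, coefficients, hiVec, litterFactor,
                             carbonFraction)
  residual <- abs(satGpp - statHat)
  if (residual > gMid + 1e-9 * max(satGpp, 1))
    warning("calibration objective exceeds its midpoint-start value")
  atBound <- (abs(hiVec - cf$hi_lower) < 1e-12 |
              abs(hiVec - cf$hi_upper) < 1e-12) & free
  structure(list(hi = hiVec, s = sHat, residual_z = residual,
                 at_bound = atBound[free], objective_evals = evals,
                 stat_gpp = statHat),
            class = "CalibrationResult")
}

#' Calibrate every retained district of one season-year
#'
#' @param districtGpp data.frame from [aggregateDistricts()] (needs
#'   `district_id`, `sat_gpp_total_gC`), already filtered to retained
#'   districts.
#' @param records crop-statistics data.frame (`district_id`, `crop`,
#'   `production_t`, optionally `year`, `season`).
#' @param coefficients,method,litterFactor,carbonFraction,tol passed to
#'   [calibrateHi()].
#' @return data.frame in long form: `district_id`, `crop`, `hi`,
#'   `at_bound`, `residual_z_gC`, `stat_gpp_gC`, `sat_gpp_gC`,
#'   `objective_evals`.
#' @export
calibrateDistricts <- function(districtGpp, records, coefficients,
                               method = "bisection", litterFactor = 1.15,
                               carbonFraction = 1, tol = 1e-10) {
  out <- lapply(seq_len(nrow(districtGpp)), function(i) {
    d <- districtGpp$district_id[i]
    rec <- records[records$district_id == d, , drop = FALSE]
    if (nrow(rec) == 0L) return(NULL)
    fit <- calibrateHi(districtGpp$sat_gpp_total_gC[i], rec, coefficients,
                       method = method, litterFactor = litterFactor,
                       carbonFraction = carbonFraction, tol = tol)
    cf <- .coefRow(coefficients, rec$crop)
    ab <- rep(FALSE, nrow(rec)); ab[is.na(cf$fixed_hi)] <- fit$at_bound
    data.frame(district_id = d, crop = rec$crop, hi = unname(fit$hi),
               at_bound = ab, residual_z_gC = fit$residual_z,
               stat_gpp_gC = fit$stat_gpp,
               sat_gpp_gC = districtGpp$sat_gpp_total_gC[i],
               objective_evals = fit$objective_evals)
  })
  do.call(rbind, out)
}

#' Next-year validation with previous-year coefficients
#'
#' Applies the harvest indices calibrated in one year to the following
#' year's production statistics via [productionToGpp()] — no optimization
#' — and pairs the result with the satellite district GPP of that year.
#' Districts without previous-year coefficients are skipped with a message.
#'
#' @param calib long calibration data.frame from [calibrateDistricts()].
#' @param nextRecords next-year crop statistics (`district_id`, `crop`,
#'   `production_t`).
#' @param nextDistrictGpp next-year [aggregateDistricts()] output.
#' @param coefficients a "CropCoefficients" table.
#' @param litterFactor,carbonFraction see [productionToGpp()].
#' @return data.frame: `district_id`, `sat_gpp_gC`, `stat_gpp_gC`.
#' @export
validateNextYear <- function(calib, nextRecords, nextDistrictGpp,
                             coefficients, litterFactor = 1.15,
                             carbonFraction = 1) {
  out <- lapply(seq_len(nrow(nextDistrictGpp)), function(i) {
    d <- nextDistrictGpp$district_id[i]
    hiRows <- calib[calib$district_id == d, , drop = FALSE]
    rec <- nextRecords[nextRecords$district_id == d, , drop = FALSE]
    if (nrow(hiRows) == 0L) {
      message("district ", d, " skipped: no previous-year coefficients")
      return(NULL)
    }
    if (nrow(rec) == 0L) return(NULL)
    hi <- stats::setNames(hiRows$hi, hiRows$crop)
    if (!all(rec$crop %in% names(hi))) {
      cfNew <- .coefRow(coefficients, setdiff(rec$crop, names(hi)))
      if (any(is.na(cfNew$fixed_hi))) {
        message("district ", d, " skipped: crop without prior coefficient")
        return(NULL)
      }
    }
    data.frame(district_id = d,
               sat_gpp_gC = nextDistrictGpp$sat_gpp_total_gC[i],
               stat_gpp_gC = productionToGpp(rec, coefficients, hi,
                                             litterFactor, carbonFraction))
  })
  do.call(rbind, out)
}

#' Calibration/validation agreement metrics
#'
#' `computeR2` is the squared Pearson correlation between satellite and
#' statistics-derived district GPP; it is undefined (NA, with a warning)
#' when either margin has zero variance. `computeNrmse` is the root mean
#' squared difference expressed as a percentage of the mean
#' statistics-derived GPP.
#'
#' @param pairs data.frame with columns `sat_gpp_gC` and `stat_gpp_gC`
#'   (one row per district).
#' @return scalar R2 in [0, 1] (or NA), or nRMSE in percent.
#' @export
computeR2 <- function(pairs) {
  stopifnot(all(c("sat_gpp_gC", "stat_gpp_gC") %in% names(pairs)),
            nrow(pairs) >= 2L)
  if (stats::sd(pairs$sat_gpp_gC) == 0 || stats::sd(pairs$stat_gpp_gC) == 0) {
    warning("zero variance: R2 undefined")
    return(NA_real_)
  }
  stats::cor(pairs$sat_gpp_gC, pairs$stat_gpp_gC)^2
}

#' @rdname computeR2
#' @export
computeNrmse <- function(pairs) {
  stopifnot(all(c("sat_gpp_gC", "stat_gpp_gC") %in% names(pairs)),
            nrow(pairs) >= 2L)
  m <- mean(pairs$stat_gpp_gC)
  if (m == 0) stop("mean statistics GPP is zero: nRMSE undefined")
  100 * sqrt(mean((pairs$sat_gpp_gC - pairs$stat_gpp_gC)^2)) / m
}
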