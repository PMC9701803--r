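coefOne <- cropCoefficients("rice", 0.2, 0.8, rc = 0.25, mc = 0.12)

test_that("statistics-to-GPP conversion matches hand arithmetic", {
  rec <- data.frame(crop = "rice", production_t = 100)
  # 1.15 * (100e6 / 0.5) * 1.25 * 0.88 = 2.53e8 g
  expect_equal(productionToGpp(rec, coefOne, c(rice = 0.5)), 2.53e8,
               tolerance = 1e-12)
  expect_equal(productionToGpp(data.frame(crop = "rice", production_t = 0),
                               coefOne, c(rice = 0.5)), 0)
  # additivity: splitting production across identical rows changes nothing
  rec2 <- data.frame(crop = c("rice", "wheat"), production_t = c(50, 50))
  coef2 <- cropCoefficients(c("rice", "wheat"), c(0.2, 0.2), c(0.8, 0.8),
                            rc = c(0.25, 0.25), mc = c(0.12, 0.12))
  expect_equal(productionToGpp(rec2, coef2, c(rice = 0.5, wheat = 0.5)),
               2.53e8, tolerance = 1e-12)
  expect_error(productionToGpp(rec, coefOne, c(rice = 0)), "in \\(0, 1\\)")
  expect_error(productionToGpp(data.frame(crop = "oats", production_t = 1),
                               coefOne, c(oats = 0.5)), "missing coefficients")
  # fixed-HI crops take their coefficient value automatically
  coefFix <- cropCoefficients("sugarcane", 0.6, 0.8, rc = 0.3, mc = 0.7,
                              fixed_hi = 0.69)
  expect_equal(productionToGpp(data.frame(crop = "sugarcane",
                                          production_t = 69),
                               coefFix, c()),
               1.15 * 69e6 / 0.69 * 1.3 * 0.3, tolerance = 1e-12)
})

test_that("single-crop calibration solves the closed form and clips at bounds", {
  rec <- data.frame(crop = "rice", production_t = 100)
  fit <- calibrateHi(2.53e8, rec, coefOne)
  expect_equal(unname(fit$hi["rice"]), 0.5, tolerance = 1e-9)
  expect_equal(fit$residual_z, 0, tolerance = 1e-3)   # grams, scale 2.5e8
  expect_false(any(fit$at_bound))
  # satellite GPP far above what the lower bound can produce -> clip
  hiAt <- function(hi) 1.15 * 100e6 / hi * 1.25 * 0.88
  fit2 <- calibrateHi(10 * hiAt(0.2), rec, coefOne)
  expect_equal(unname(fit2$hi["rice"]), 0.2)
  expect_true(all(fit2$at_bound))
  expect_gt(fit2$residual_z, 0)
  fit3 <- calibrateHi(0.5 * hiAt(0.8), rec, coefOne)
  expect_equal(unname(fit3$hi["rice"]), 0.8)
  expect_error(calibrateHi(1e8, rec[0, ], coefOne), "no crop records")
})

test_that("equal crops with equal bounds recover equal harvest indices", {
  coef2 <- cropCoefficients(c("rice", "wheat"), c(0.2, 0.2), c(0.8, 0.8),
                            rc = c(0.25, 0.25), mc = c(0.12, 0.12))
  rec <- data.frame(crop = c("rice", "wheat"), production_t = c(80, 80))
  fit <- calibrateHi(2 * 1.15 * 80e6 / 0.37 * 1.25 * 0.88, rec, coef2)
  expect_equal(unname(diff(fit$hi)), 0, tolerance = 1e-12)
  expect_equal(unname(fit$hi["rice"]), 0.37, tolerance = 1e-9)
})

test_that("shared-s bisection and the multivariate backend agree", {
  sc <- refScene()
  dg <- sc$truth$districtGpp
  st <- generateCropStats(sc, crops = "rice",
                          coefficients = defaultCropCoefficients(),
                          productionNoiseSd = 0,
                          shares = matrix(1, nrow(dg), 1))
  for (i in seq_len(nrow(dg))) {
    rec <- st$records[st$records$district_id == dg$district_id[i], ]
    a <- calibrateHi(dg$sat_gpp_total_gC[i], rec, defaultCropCoefficients())
    b <- calibrateHi(dg$sat_gpp_total_gC[i], rec, defaultCropCoefficients(),
                     method = "optim")
    expect_equal(unname(a$hi["rice"]), unname(b$hi["rice"]),
                 tolerance = 1e-6)
  }
})

test_that("calibration objective never exceeds its midpoint start", {
  sc <- refScene()
  dg <- sc$truth$districtGpp
  for (seed in 1:5) {
    st <- generateCropStats(sc, productionNoiseSd = 0.2, seed = 300 + seed)
    for (i in seq_len(nrow(dg))) {
      rec <- st$records[st$records$district_id == dg$district_id[i], ]
      fit <- calibrateHi(dg$sat_gpp_total_gC[i], rec,
                         defaultCropCoefficients())
      mid <- with(defaultCropCoefficients()[match(rec$crop,
                    defaultCropCoefficients()$crop), ],
                  stats::setNames((hi_lower + hi_upper) / 2, rec$crop))
      gMid <- abs(dg$sat_gpp_total_gC[i] -
                    productionToGpp(rec, defaultCropCoefficients(), mid))
      expect_lte(fit$residual_z, gMid * (1 + 1e-12))
      cf <- defaultCropCoefficients()
      cf <- cf[match(rec$crop, cf$crop), ]
      expect_true(all(fit$hi >= cf$hi_lower - 1e-12 &
                        fit$hi <= cf$hi_upper + 1e-12 | !is.na(cf$fixed_hi)))
    }
  }
})

test_that("next-year validation applies coefficients without optimization", {
  sc <- refScene()
  dg <- sc$truth$districtGpp
  st <- generateCropStats(sc, productionNoiseSd = 0)
  calib <- calibrateDistricts(dg, st$records, defaultCropCoefficients())
  # unchanged production and GPP -> residuals 0, R2 = 1
  val <- validateNextYear(calib, st$records, dg, defaultCropCoefficients())
  expect_equal(val$stat_gpp_gC, val$sat_gpp_gC, tolerance = 1e-9)
  expect_equal(computeR2(val), 1, tolerance = 1e-12)
  expect_equal(computeNrmse(val), 0, tolerance = 1e-6)
  # doubling next-year production doubles the statistics GPP
  rec2 <- st$records
  rec2$production_t <- 2 * rec2$production_t
  val2 <- validateNextYear(calib, rec2, dg, defaultCropCoefficients())
  expect_equal(val2$stat_gpp_gC, 2 * val$stat_gpp_gC, tolerance = 1e-12)
  # districts without prior coefficients are skipped with a message
  dg2 <- rbind(dg, within(dg[1, ], district_id <- 42L))
  expect_message(val3 <- validateNextYear(calib, st$records, dg2,
                                          defaultCropCoefficients()),
                 "skipped")
  expect_false(42L %in% val3$district_id)
})

test_that("R2 and nRMSE follow their definitions and degenerate contracts", {
  pairs <- data.frame(sat_gpp_gC = c(1, 2, 3), stat_gpp_gC = c(2, 4, 6))
  expect_equal(computeR2(pairs), 1)
  same <- data.frame(sat_gpp_gC = c(1, 2, 3), stat_gpp_gC = c(1, 2, 3))
  expect_equal(computeNrmse(same), 0)
  flat <- data.frame(sat_gpp_gC = c(1, 2, 3), stat_gpp_gC = c(2, 2, 2))
  expect_warning(r2 <- computeR2(flat), "zero variance")
  expect_true(is.na(r2))
  off <- data.frame(sat_gpp_gC = c(1, 2), stat_gpp_gC = c(2, 3))
  expect_equal(computeNrmse(off), 100 * 1 / 2.5)
})
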