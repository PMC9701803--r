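test_that("fPAR follows the clamped linear NDVI relation", {
  expect_equal(computeFpar(0.5), 0.452, tolerance = 1e-12)
  expect_equal(computeFpar(0.168 / 1.24), 0)          # root of the line
  expect_equal(computeFpar(0.05), 0)                  # clamped below
  expect_equal(computeFpar(1, fparParams(1.24, 0.168)), 1)  # clamped above
  expect_true(is.na(computeFpar(NA_real_)))
  expect_error(computeFpar(1.2), "NDVI")
  m <- matrix(c(0.5, NA, -0.2, 0.9), 2, 2)
  out <- computeFpar(m)
  expect_identical(dim(out), dim(m))
  expect_equal(out[1, 1], 0.452)
})

test_that("LSWI is the NIR/SWIR normalized difference with nodata contract", {
  expect_equal(computeLswi(0.3, 0.1), 0.5)
  expect_equal(computeLswi(0.2, 0.2), 0)
  expect_equal(computeLswi(0.4, 0), 1)
  expect_true(is.na(computeLswi(0, 0)))
  expect_error(computeLswi(-0.1, 0.2), "nonnegative")
})

test_that("water scalar is the clamped LSWI ratio", {
  expect_equal(computeWscalar(0.3, 0.3), 1)
  expect_equal(computeWscalar(-1, 0.5), 0)
  expect_equal(computeWscalar(0, 0.4), 1 / 1.4, tolerance = 1e-12)
  expect_true(is.na(computeWscalar(0.2, -1)))  # degenerate pixel
  expect_error(computeWscalar(1.5, 0.2), "LSWI")
})

test_that("temperature scalar matches hand arithmetic and cardinal limits", {
  expect_equal(computeTscalar(25, c3Params()), 1)
  expect_equal(computeTscalar(5, c3Params()), 0)
  expect_equal(computeTscalar(40, c3Params()), 0)
  expect_equal(computeTscalar(15, c3Params()), 250 / 350, tolerance = 1e-12)
  expect_equal(computeTscalar(-5, c3Params()), 0)    # outside range forced 0
  expect_equal(computeTscalar(50, c4Params()), 0)
  ts <- computeTscalar(seq(-10, 60, by = 0.25), c3Params())
  expect_true(all(ts >= 0 & ts <= 1))
})

test_that("pathway mixing is a convex combination of the LUE maxima", {
  expect_equal(computeLueMax(1, 0), 1.388)
  expect_equal(computeLueMax(0, 1), 1.542)
  expect_equal(computeLueMax(0.5, 0.5), 1.465, tolerance = 1e-12)
  p <- runif(50)
  eps <- computeLueMax(p, 1 - p)
  expect_true(all(eps >= 1.388 - 1e-12 & eps <= 1.542 + 1e-12))
  expect_error(computeLueMax(0.5, 0.4), "equal 1")
})

test_that("composite GPP multiplies efficiency, fPAR and PAR", {
  unitPars <- vpmParams(c3 = pathwayParams(5, 40, 25, 1),
                        c4 = pathwayParams(8, 42, 30, 1))
  ndvi <- (0.5 + 0.168) / 1.24     # fPAR = 0.5
  g <- computeGppComposite(ndvi, lswi = 0.3, lswiMax = 0.3, par16d = 200,
                           tday = 25, propC3 = 1, propC4 = 0,
                           params = unitPars)
  expect_equal(g, 100, tolerance = 1e-12)
  expect_equal(computeGppComposite(0.05, 0.3, 0.3, 200, 25, 1, 0), 0)
  expect_true(is.na(computeGppComposite(NA, 0.3, 0.3, 200, 25, 1, 0)))
  # linear in PAR holding all else fixed
  g2 <- computeGppComposite(0.6, 0.1, 0.4, c(100, 200, 400), 22, 0.7, 0.3)
  expect_equal(g2[2] / g2[1], 2, tolerance = 1e-12)
  expect_equal(g2[3] / g2[1], 4, tolerance = 1e-12)
  expect_true(all(g2 >= 0))
})

test_that("pure-C3 stack output matches a scalar single-pathway oracle", {
  set.seed(42)
  sc <- refScene()
  n <- nLayers(sc$ndviStack)
  lswiMax <- rasterValues(computeLswiMax(sc$lswiStack))
  ones <- setRasterValues(sc$propC3,
                          matrix(1, nrow(lswiMax), ncol(lswiMax)))
  zeros <- setRasterValues(sc$propC3,
                           matrix(0, nrow(lswiMax), ncol(lswiMax)))
  gpp <- computeGppStack(sc$ndviStack, sc$lswiStack, sc$parStack,
                         sc$tdayStack, ones, zeros)
  pix <- cbind(sample(nrow(lswiMax), 10, replace = TRUE),
               sample(ncol(lswiMax), 10, replace = TRUE))
  for (k in seq_len(10)) {
    r <- pix[k, 1]; c <- pix[k, 2]
    i <- sample(n, 1)
    ndvi <- rasterValues(getLayer(sc$ndviStack, i))[r, c]
    lswi <- rasterValues(getLayer(sc$lswiStack, i))[r, c]
    par <- rasterValues(getLayer(sc$parStack, i))[r, c]
    t <- rasterValues(getLayer(sc$tdayStack, i))[r, c]
    # independent scalar chain with the published C3 constants
    fpar <- min(max(1.24 * ndvi - 0.168, 0), 1)
    tsc <- (t - 40) * (t - 5) / ((t - 40) * (t - 5) - (t - 25)^2)
    if (t <= 5 || t >= 40) tsc <- 0
    wsc <- min(max((1 + lswi) / (1 + lswiMax[r, c]), 0), 1)
    expect_equal(rasterValues(getLayer(gpp, i))[r, c],
                 1.388 * tsc * wsc * fpar * par, tolerance = 1e-12)
  }
})

test_that("seasonal integration sums composites and applies the mask", {
  mats <- replicate(3, matrix(10, 4, 5), simplify = FALSE)
  st <- tinyStack(mats, "GPP")
  mask <- tinyRaster(matrix(1, 4, 5))
  out <- rasterValues(integrateSeason(st, mask))
  expect_true(all(out == 30))
  maskM <- matrix(1, 4, 5); maskM[2, ] <- 0
  out2 <- rasterValues(integrateSeason(st, tinyRaster(maskM)))
  expect_true(all(is.na(out2[2, ])))
  expect_true(all(out2[-2, ] == 30))
  # all-zero mask -> all nodata; single layer -> identity
  expect_true(all(is.na(rasterValues(
    integrateSeason(st, tinyRaster(matrix(0, 4, 5)))))))
  one <- tinyStack(list(matrix(runif(20), 4, 5)), "GPP")
  expect_equal(rasterValues(integrateSeason(one, mask)),
               rasterValues(getLayer(one, 1)))
  expect_error(integrateSeason(st, agRaster(matrix(1, 3, 5))),
               "co-registered")
})

test_that("seasonal integral conserves the per-composite sum", {
  sc <- refScene()
  gpp <- computeGppStack(sc$ndviStack, sc$lswiStack, sc$parStack,
                         sc$tdayStack, sc$propC3, sc$propC4)
  tot <- integrateSeason(gpp, sc$croplandMask)
  manual <- Reduce(`+`, lapply(seq_len(nLayers(gpp)),
                               function(i) rasterValues(getLayer(gpp, i))))
  sel <- !is.na(rasterValues(tot))
  expect_true(all(relDiff(rasterValues(tot)[sel], manual[sel]) < 1e-12))
})

test_that("climate compositing converts and averages per 16-day window", {
  start <- as.Date("2001-06-01")
  days <- start + 0:31
  cc <- compositeClimate(days, rep(100, 32), rep(30, 32), rep(10, 32),
                         c(start, start + 16))
  expect_equal(cc$par_mj, c(138.24, 138.24), tolerance = 1e-12)
  expect_equal(cc$tday_c, c(25, 25), tolerance = 1e-12)   # 0.75/0.25 weights
  cc2 <- compositeClimate(days, rep(100, 32), rep(30, 32), rep(10, 32),
                          c(start, start + 16), tdayWeights = c(0.5, 0.5))
  expect_equal(cc2$tday_c[1], 20)
  # a missing day flags the window nodata
  cc3 <- compositeClimate(days[-5], rep(100, 31), rep(30, 31), rep(10, 31),
                          c(start, start + 16))
  expect_true(is.na(cc3$par_mj[1]) && is.na(cc3$tday_c[1]))
  expect_false(is.na(cc3$par_mj[2]))
})

test_that("resampling preserves constants, ramps and nodata", {
  coarse <- agRaster(matrix(7, 5, 5), xmin = 75, ymax = 22, res = 0.02)
  target <- agRaster(matrix(NA_real_, 20, 20), xmin = 75, ymax = 22,
                     res = 0.005)
  expect_true(all(rasterValues(resampleToGrid(coarse, target)) == 7))
  # identity when the grids coincide
  m <- matrix(runif(25), 5, 5); m[3, 3] <- NA
  r <- agRaster(m, xmin = 75, ymax = 22, res = 0.02)
  expect_equal(rasterValues(resampleToGrid(r, r)), m)
  expect_equal(rasterValues(resampleToGrid(r, r, method = "nearest")), m)
  # a linear ramp interpolates to its exact values at interior cell centers
  ramp <- agRaster(outer(rep(1, 5), seq(0, 4)), xmin = 75, ymax = 22,
                   res = 0.02)
  out <- resampleToGrid(ramp, target)
  lonC <- cellCenters(target)$lon
  expected <- pmin(pmax((lonC - (75 + 0.01)) / 0.02, 0), 4)
  expect_equal(rasterValues(out)[10, ], expected, tolerance = 1e-10)
  far <- agRaster(matrix(1, 5, 5), xmin = 80, ymax = 22, res = 0.02)
  expect_error(resampleToGrid(far, target), "cover")
})

test_that("seasonal LSWI maximum ignores nodata and keeps all-nodata pixels", {
  m1 <- matrix(-0.1, 2, 2); m2 <- matrix(0.3, 2, 2); m3 <- matrix(0.2, 2, 2)
  m2[1, 1] <- NA; m1[2, 2] <- NA; m2[2, 2] <- NA; m3[2, 2] <- NA
  mx <- rasterValues(computeLswiMax(tinyStack(list(m1, m2, m3), "LSWI")))
  expect_equal(mx[1, 2], 0.3)
  expect_equal(mx[1, 1], 0.2)          # max of the remaining layers
  expect_true(is.na(mx[2, 2]))         # nodata in every layer
  one <- tinyStack(list(m1), "LSWI")
  expect_equal(rasterValues(computeLswiMax(one)), m1)
})
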