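# shared fixtures, built in code at test time

tinyRaster <- function(m) agRaster(m, xmin = 75, ymax = 22, res = 0.005)

tinyStack <- function(mats, varname = "x", units = "") {
  dates <- as.Date("2001-06-01") + (seq_along(mats) - 1L) * 16L
  compositeStack(lapply(mats, tinyRaster), dates, varname, units)
}

# the reference noiseless desk-scale scene, built once per test run
refScene <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateScene(sceneConfig(noiseSdNdvi = 0, rngSeed = 11L))
    cache
  }
})

relDiff <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)
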