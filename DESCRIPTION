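Package: agrigpp
Title: Seasonal Agricultural Gross Primary Productivity from a Light-Use-Efficiency Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-level vegetation photosynthesis (VPM) light-use-efficiency
    modelling of seasonal cropland gross primary productivity (GPP), with
    dynamic C3/C4-weighted maximum light-use efficiency, 16-day climate
    compositing and bilinear resampling, district-level zonal aggregation,
    calibration of crop harvest indices against production statistics by
    bounded optimization, next-year validation with R2 and nRMSE, and
    pixel-level normalized yield (NGPPCY) downscaling. Includes a synthetic
    scene generator with known ground truth so every stage is testable
    without satellite or government data, plus plain-text raster (ESRI
    ASCII grid) input/output and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
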