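---
title: "Seasonal cropland GPP with agrigpp: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal cropland GPP with agrigpp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrigpp)
```

## The model

`agrigpp` estimates seasonal gross primary productivity (GPP) of cropland
with a light-use-efficiency model of the vegetation photosynthesis (VPM)
family. For every pixel and 16-day composite,

$$GPP = \varepsilon \cdot fPAR \cdot PAR, \qquad
  \varepsilon = \varepsilon^* \cdot T_{scalar} \cdot W_{scalar} \cdot P_{scalar}$$

with PAR accumulated over the window (MJ m^-2^) and GPP in gC m^-2^ per
composite. The pieces:

* **fPAR** — the chlorophyll-absorbed fraction of PAR is linear in NDVI,
  $fPAR = a \cdot NDVI - b$ with defaults $a = 1.24$, $b = 0.168$
  (`computeFpar`). The linear form is negative below $NDVI = b/a \approx
  0.135$; we clamp to $[0, 1]$ so sparse canopies yield zero rather than
  negative GPP.
* **Maximum light-use efficiency** — croplands mix C3 and C4 species, whose
  unstressed efficiencies differ. Each pixel carries season-specific
  fractions $prop_{C3} + prop_{C4} = 1$ and
  $\varepsilon^* = LUE_{C3}\,prop_{C3} + LUE_{C4}\,prop_{C4}$
  (`computeLueMax`), with defaults $LUE_{C3} = 1.388$ and
  $LUE_{C4} = 1.542$ gC MJ^-1^ APAR.
* **Temperature scalar** —
  $$T_{scalar} = \frac{(T - T_{max})(T - T_{min})}
    {(T - T_{max})(T - T_{min}) - (T - T_{opt})^2}$$
  with cardinal temperatures (5, 40, 25) °C for C3 and (8, 42, 30) °C for
  C4 crops. Outside $(T_{min}, T_{max})$ the raw expression is negative or
  exceeds 1; we force it to 0 there, consistent with common VPM practice
  (`computeTscalar`). Because a mixed pixel has no single pathway response,
  $T_{scalar}$ is evaluated under both parameter sets and mixed with the
  same $prop_{C3}/prop_{C4}$ weights as $\varepsilon^*$.
* **Water scalar** — from the land surface water index
  $LSWI = (NIR - SWIR)/(NIR + SWIR)$ (`computeLswi`),
  $W_{scalar} = (1 + LSWI)/(1 + LSWI_{max})$ clamped to $[0,1]$
  (`computeWscalar`). $LSWI_{max}$ is not uniquely defined in the
  literature; we define it as the per-pixel maximum LSWI over the season's
  composites, ignoring nodata (`computeLswiMax`). A pixel with
  $LSWI_{max} = -1$ is degenerate and returns nodata.
* **Phenology scalar** — $P_{scalar} = 1$: the dominant crops (rice, wheat)
  are in full leaf during both cropping seasons considered.

Composite GPP is summed over the season and non-agricultural pixels are
nullified with a static cropland mask (`integrateSeason`). Seasons are the
Indian cropping calendar: monsoon/kharif (June–October) and winter/rabi
(November–March, labelled by its starting year); a 16-day window belongs to
a season iff its start date falls inside the span.

### Climate preprocessing

Daily PAR (W m^-2^) and daily min/max 2-m air temperature arrive on a
coarser grid than the vegetation indices. `compositeClimate` synchronises
them with the 16-day model interval: window PAR is
$\sum_{days} \bar{PAR} \times 0.0864$ MJ m^-2^ (0.0864 MJ per W-day), and
the window daytime mean temperature averages the daily estimator
$0.75\,T_{max} + 0.25\,T_{min}$. The 0.75/0.25 weighting approximates a
daytime mean, which sits above the diurnal midpoint; the plain midpoint
$(T_{max}+T_{min})/2$ is available through `vpmParams(tdayWeights =
c(0.5, 0.5))`. A window missing any day is flagged nodata. Scalars are
computed once per 16-day composite (not daily-then-averaged); the choice is
configurable in principle through the daily series interface.
`resampleToGrid` then interpolates the coarse fields to the model grid,
bilinear by default (nearest-neighbour optionally), holding values at the
edge beyond the outermost coarse cell centers and propagating nodata
through the interpolation stencil.

## From crop statistics to GPP and back

Government statistics report production $PROD_i$ (tonnes) and area (Ha) per
district, season, year and crop. Production converts to gross carbon via
per-crop coefficients — harvest index $HI_i$ (economic yield over
above-ground biomass), respiration coefficient $RC_i$ (applied as $1 +
RC_i$) and moisture content $MC_i$ (removed as $1 - MC_i$):

$$GPP_{stat} = 1.15 \sum_i \frac{PROD_i}{HI_i}\,(1 + RC_i)\,(1 - MC_i)$$

with tonnes converted to grams (`productionToGpp`). The 1.15 multiplier
accounts for litterfall and energy-efficiency losses. Whether a
biomass-to-carbon fraction (≈ 0.45) is folded into that multiplier is
ambiguous in the source formulation; we default `carbonFraction = 1` so the
implementation matches the relation literally and expose the factor as an
argument for unit-closure experiments.

### Calibration

For each district–season–year independently, calibration seeks the
harvest-index vector, within per-crop literature bounds, minimising
$Z = |Sat.GPP_D - GPP_{stat}(HI)|$, where $Sat.GPP_D$ is the satellite GPP
summed over the district's cropland pixels times their spherical pixel
areas (`aggregateDistricts`). The printed form of the objective omits the
difference operator; we read it as the absolute difference, which the
accompanying prose ("minimises the difference") supports.

One scalar equation cannot identify several independent harvest indices.
The default solver therefore parametrises every free index on a shared
line, $HI_i = lower_i + s\,(upper_i - lower_i)$ with one $s \in [0,1]$.
$GPP_{stat}$ is strictly decreasing in $s$, so a monotone bisection
(terminating at $10^{-10}$ on $s$, followed by a few secant polishing steps
that bring the root to machine precision) finds the unique interior zero;
when none exists the solution clips to the nearer bound and the `at_bound`
flag is set, with ties at an exact bound resolving to the bound. Crops
with a fixed harvest index (sugarcane, 0.69) are held constant. A
multivariate bounded quasi-Newton backend (L-BFGS-B with analytic
gradient, started from the bound midpoints — the R analogue of a
constrained MATLAB-style minimiser) is available via `method = "optim"`;
on single-crop districts the two backends agree to well below 1e-6.
Every run checks that the final objective does not exceed its value at the
midpoint start.

Validation applies the previous year's calibrated coefficients to the next
year's statistics with no optimization (`validateNextYear`); agreement is
summarised by the squared Pearson correlation $R^2$ and by
$nRMSE = 100 \times RMSE / \overline{GPP_{stat}}$ (the normaliser is the
mean statistics-derived GPP; the source does not state one, and the mean of
the reference series is the common convention).

### District filters

Districts with under 75,000 Ha total cropped area, or where the modelled
crops cover under 30% of it, are excluded before calibration
(`filterDistricts`). The considered-crop share is computed per season
(gross cropped area); both thresholds are inclusive. Desk-scale synthetic
scenes cover a tiny fraction of a real district's area, so toy pipeline
configurations pass a `minAreaHa` scaled to the scene — the default
thresholds remain the operational ones.

### Pixel-level normalized yield (NGPPCY)

District yield statistics are redistributed to pixels in proportion to GPP:
$NGPPCY(p) = yield_d \cdot GPP(p) / \overline{GPP}_d$ in t Ha^-1^
(`computeNgppcy`). Two readings of the district reference were possible;
we use the single-year unweighted mean over the district's cropland pixels,
which makes the defining conservation property exact — the unweighted
district mean of NGPPCY equals the district yield. The district yield is
the crop-combined ratio $\sum PROD / \sum area$ over the considered crops
(`districtCombinedYield`). An area-weighted mean and a multi-year
reference would both break the exact conservation and are left to the
caller (the inputs are plain rasters and tables, so either variant is a
few lines).

## The synthetic scene generator

Real inputs (MODIS-class vegetation indices, reanalysis climate, cropland
masks, government statistics) are unavailable offline, so `generateScene`
builds a self-consistent scene with known truth:

* **NDVI** follows a scaled beta-shaped pulse over the season's composites
  on cropland — unimodal, crop-like phenology — with peak position (0.40 to
  0.60 of the season) and peak height (0.65 to 0.85) jittered per district
  and ±10% amplitude variation per pixel; off-cropland pixels sit at a flat
  0.12. Optional additive Gaussian noise (`noiseSdNdvi`, default 0.02) is
  applied to the emitted stack only.
* **LSWI** is NDVI-correlated ($0.75\,NDVI - 0.18$) with additive noise at
  half the NDVI noise SD, clipped to $[-1, 1]$ — the simplest structure
  that exercises the water scalar.
* **Climate** is generated as smooth daily PAR and min/max temperature
  series on a grid `climateDownscaleFactor` times coarser (default 4),
  composited with `compositeClimate` and resampled with `resampleToGrid` —
  the same code paths the real pipeline would use.
* **C3/C4 fractions** form a smooth spatial field with $prop_{C3} +
  prop_{C4} = 1$ everywhere; the cropland mask is a seeded 88% Bernoulli
  field (each district guaranteed at least three cropland pixels);
  districts are rectangular blocks.
* **Truth** — the true seasonal GPP raster is the VPM run forward on the
  noise-free drivers, and district totals follow by zonal aggregation with
  the same pixel-area function, so generator and pipeline cannot disagree
  by construction of the geometry.

`generateCropStats` inverts the statistics relation: each district's true
GPP total is partitioned across crops by Dirichlet(3) shares and converted
to production at the true harvest indices, then perturbed by multiplicative
lognormal noise (meanlog 0, sdlog = `productionNoiseSd`), which keeps
production positive. The true indices are drawn on the same shared-s
family the default solver searches (one $s_{true}$ uniform in (0.2, 0.8)
applied to every free crop's bounds): with truth strictly inside the
bounds and zero noise, calibration must recover every index exactly, and
the test suite checks recovery to 1e-6 and better. Truth off that family
would be unidentifiable from one equation per district — a limitation of
the calibration design itself, not of the generator.

**What the generator does not emulate:** orbital/QA artifacts, cloud gaps,
real phenology calendars, mixed-date composites, inter-annual mask change,
spatially correlated statistical errors, or real district geometries.
Passing tests therefore demonstrate the internal consistency and numerical
correctness of every stage, not skill against real observations.

## Numerical conventions

* Nodata is IEEE NaN/NA in memory and −9999 on disk; rasters travel as
  ESRI ASCII grids (plain text, full double precision, bit-exact round
  trip) on a north-up, pixel-is-area WGS84 lon/lat grid.
* Pixel areas use the spherical formula at the cell-center latitude with
  the authalic radius 6371008.8 m.
* fPAR, $T_{scalar}$, $W_{scalar}$ are clamped to $[0,1]$; GPP is
  nonnegative wherever defined and nodata propagates through every stage.
* Bisection terminates at $10^{-10}$ on $s$ plus secant polish; the
  L-BFGS-B backend minimises the squared relative residual with
  `factr = 10` and an analytic gradient.
* CSV artifacts are written with 9 significant digits and snake_case
  columns; reruns with the same configuration and seed are byte-identical.

## Problem sizes

The reference desk-scale scene is a 20 × 20 grid of 0.005° (~500 m) cells,
8 composites, 6 districts and 3 free-HI crops; the noise study uses
production noise SD ∈ {0, 0.05, 0.15} over 20 seeds. These sizes keep the
full suite under a minute while leaving every stage non-trivial (climate
on a 5 × 5 coarse grid, ~50–60 cropland pixels per district).

## A worked run

```{r pipeline}
cfg <- pipelineConfig(scene = sceneConfig(noiseSdNdvi = 0.01,
                                          noiseSdProduction = 0.03),
                      minAreaHa = 500)   # scaled to the toy scene
res <- runPipeline(cfg, tempfile("agrigpp"), seed = 42)
str(res$metrics)
head(res$calib)
```

With mild noise the calibration fit is near-perfect by construction (each
district has one free degree of freedom against one equation, so residuals
are only nonzero when the solution clips at a bound); the validation-year
metrics, which involve no optimization, are the meaningful measure of how
noise propagates.

## Known limitations

* No EVI driver, VIIRS ingestion, QA screening or gap-filling; composites
  are assumed pre-aligned across variables.
* Calibration shares no information across districts or years; sparse or
  zero-production districts fall back to bound clipping.
* The shared-s parametrisation trades multi-crop identifiability for
  determinism; the multivariate backend will generally land on a different
  (equally residual-minimal) point of the solution set when several crops
  are free.
* Label rasters stand in for district polygons; there is no polygon zonal
  statistics path.
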