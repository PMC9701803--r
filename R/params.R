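#' fPAR linear-relation parameters
#'
#' The fraction of photosynthetically active radiation absorbed by
#' chlorophyll is modelled as a linear function of NDVI,
#' \eqn{fPAR = a \cdot NDVI - b}, clamped to [0, 1].
#'
#' @slot a dimensionless slope (> 0), default 1.24.
#' @slot b dimensionless intercept, default 0.168.
#' @aliases FparParams-class
#' @exportClass FparParams
setClass("FparParams", representation(a = "numeric", b = "numeric"),
  validity = function(object) {
    if (length(object@a) != 1L || length(object@b) != 1L)
      return("'a' and 'b' must be scalars")
    if (!is.finite(object@a) || object@a <= 0)
      return("slope 'a' must be positive")
    TRUE
  })

#' @describeIn FparParams-class constructor with the package defaults.
#' @param a,b slope and intercept of the NDVI-to-fPAR relation.
#' @export
fparParams <- function(a = 1.24, b = 0.168) new("FparParams", a = a, b = b)

#' Photosynthetic-pathway temperature and efficiency parameters
#'
#' Cardinal temperatures of the temperature down-regulation scalar and the
#' maximum light-use efficiency for one photosynthetic pathway. Package
#' defaults: C3 crops (Tmin 5, Tmax 40, Topt 25 degC; LUE 1.388 gC/MJ APAR)
#' and C4 crops (8, 42, 30 degC; 1.542 gC/MJ APAR).
#'
#' @slot tMin,tMax,tOpt cardinal temperatures in degC, tMin < tOpt < tMax.
#' @slot lueMax maximum light-use efficiency in gC per MJ APAR (> 0).
#' @slot pathway "C3" or "C4" tag.
#' @aliases PathwayParams-class
#' @exportClass PathwayParams
setClass("PathwayParams",
  representation(tMin = "numeric", tMax = "numeric", tOpt = "numeric",
                 lueMax = "numeric", pathway = "character"),
  validity = function(object) {
    msg <- character()
    if (!(object@tMin < object@tOpt && object@tOpt < object@tMax))
      msg <- c(msg, "need tMin < tOpt < tMax")
    if (!is.finite(object@lueMax) || object@lueMax <= 0)
      msg <- c(msg, "'lueMax' must be positive")
    if (length(msg)) msg else TRUE
  })

#' @describeIn PathwayParams-class construct an arbitrary pathway.
#' @param tMin,tMax,tOpt cardinal temperatures (degC).
#' @param lueMax maximum light-use efficiency (gC/MJ APAR).
#' @param pathway label, "C3" or "C4".
#' @export
pathwayParams <- function(tMin, tMax, tOpt, lueMax, pathway = "C3")
  new("PathwayParams", tMin = tMin, tMax = tMax, tOpt = tOpt,
      lueMax = lueMax, pathway = pathway)

#' @describeIn PathwayParams-class default C3-crop parameters.
#' @export
c3Params <- function() pathwayParams(5, 40, 25, 1.388, "C3")

#' @describeIn PathwayParams-class default C4-crop parameters.
#' @export
c4Params <- function() pathwayParams(8, 42, 30, 1.542, "C4")

setMethod("show", "PathwayParams", function(object) {
  cat(sprintf(
    "PathwayParams %s: Tmin %.6g, Topt %.6g, Tmax %.6g degC; LUEmax %.6g gC/MJ\n",
    object@pathway, object@tMin, object@tOpt, object@tMax, object@lueMax))
})

#' Bundle of VPM model parameters
#'
#' Collects the fPAR relation, the two pathway parameter sets and the fixed
#' phenology scalar into one object passed through the GPP pipeline.
#' `tdayWeights` gives the (Tmax, Tmin) weights of the daytime-mean
#' temperature estimator used when compositing daily climate;
#' the default 0.75/0.25 weights daytime hours more heavily, and
#' c(0.5, 0.5) gives the plain midpoint.
#'
#' @param fpar an \linkS4class{FparParams}.
#' @param c3,c4 \linkS4class{PathwayParams} for the two pathways.
#' @param pScalar phenology scalar, fixed at 1 (full leaf emergence of the
#'   dominant crops during both seasons).
#' @param tdayWeights length-2 numeric (weight of Tmax, weight of Tmin),
#'   must sum to 1.
#' @return list of class "VpmParams".
#' @export
vpmParams <- function(fpar = fparParams(), c3 = c3Params(), c4 = c4Params(),
                      pScalar = 1, tdayWeights = c(0.75, 0.25)) {
  stopifnot(is(fpar, "FparParams"), is(c3, "PathwayParams"),
            is(c4, "PathwayParams"),
            length(tdayWeights) == 2L, abs(sum(tdayWeights) - 1) < 1e-9,
            pScalar >= 0, pScalar <= 1)
  structure(list(fpar = fpar, c3 = c3, c4 = c4, pScalar = pScalar,
                 tdayWeights = tdayWeights), class = "VpmParams")
}
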