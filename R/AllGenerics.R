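#' Analysing scales of an object
#'
#' @param x a ScaleSpace, WtmmSkeleton or PartitionFunctions object.
#' @return numeric vector of scales in pixels.
#' @export
setGeneric("scales", function(x) standardGeneric("scales"))

#' @rdname scales
#' @export
setMethod("scales", "ScaleSpace", function(x) x@scales)

#' @rdname scales
#' @export
setMethod("scales", "WtmmSkeleton", function(x) x@scales)

#' @rdname scales
#' @export
setMethod("scales", "PartitionFunctions", function(x) x@scales)

#' Modulus field at one scale
#'
#' @param x a [ScaleSpace-class].
#' @param i scale index (1-based into `scales(x)`).
#' @return matrix of nonnegative modulus values.
#' @export
setGeneric("modulus", function(x, i) standardGeneric("modulus"))

#' @rdname modulus
#' @export
setMethod("modulus", "ScaleSpace", function(x, i) x@modulus[[i]])

#' Argument (gradient direction) field at one scale
#'
#' @param x a [ScaleSpace-class].
#' @param i scale index.
#' @return matrix of angles in (-pi, pi].
#' @export
setGeneric("argument", function(x, i) standardGeneric("argument"))

#' @rdname argument
#' @export
setMethod("argument", "ScaleSpace", function(x, i) x@argument[[i]])

#' Per-scale border margin of a scale space
#'
#' @param x a [ScaleSpace-class].
#' @return integer vector, `ceiling(3 * a)` per scale.
#' @export
borderMargin <- function(x) x@borderMargin

#' Long-format samples of a skeleton
#'
#' @param x a [WtmmSkeleton-class].
#' @return data.frame with one row per (line, scale).
#' @export
skeletonSamples <- function(x) x@samples

#' Number of lines in a skeleton
#'
#' @param x a [WtmmSkeleton-class].
#' @return integer count of space-scale lines.
#' @export
nLines <- function(x) length(unique(x@samples$line))

#' Anchors (smallest-scale positions) of skeleton lines
#'
#' @param x a [WtmmSkeleton-class].
#' @param lines optional integer vector restricting to a line subset.
#' @return data.frame with columns `line`, `x`, `y`, `scale`.
#' @export
anchors <- function(x, lines = NULL) {
  s <- x@samples
  if (!is.null(lines)) s <- s[s$line %in% lines, , drop = FALSE]
  if (nrow(s) == 0)
    return(data.frame(line = integer(), x = numeric(), y = numeric(),
                      scale = numeric()))
  s <- s[order(s$line, s$scaleIdx), ]
  first <- !duplicated(s$line)
  data.frame(line = s$line[first], x = s$x[first], y = s$y[first],
             scale = s$scale[first])
}

#' Microcalcification-class line ids of a detection result
#'
#' @param x a [DetectionResult-class].
#' @return integer vector of line ids.
#' @export
mcLines <- function(x) x@mcLines

#' Background-class line ids of a detection result
#'
#' @param x a [DetectionResult-class].
#' @return integer vector of line ids.
#' @export
backgroundLines <- function(x) x@backgroundLines

#' Support dimension of a singularity spectrum
#'
#' The fractal dimension of the support of singularities, read at `q = 0`.
#'
#' @param x a [SingularitySpectrum-class].
#' @return numeric scalar (NA when undefined).
#' @export
supportDimension <- function(x) x@DF

#' Mean of a Beta distribution
#'
#' @param x a [BetaSpec-class].
#' @return `alpha / (alpha + beta)`.
#' @export
betaMean <- function(x) x@alpha / (x@alpha + x@beta)

#' Standard deviation of a Beta distribution
#'
#' @param x a [BetaSpec-class].
#' @return numeric scalar.
#' @export
betaSd <- function(x) {
  ab <- x@alpha + x@beta
  sqrt(x@alpha * x@beta / (ab^2 * (ab + 1)))
}

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage: %d x %d pixels (w x h), bit depth %s\n",
              ncol(object), nrow(object),
              ifelse(is.na(object@bitDepth), "NA", object@bitDepth)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@.Data), max(object@.Data)))
})

setMethod("show", "ScaleSpace", function(object) {
  cat(sprintf("ScaleSpace: %d scales in [%.3g, %.3g] px on a %d x %d image\n",
              length(object@scales), min(object@scales), max(object@scales),
              object@imageDim[2], object@imageDim[1]))
})

setMethod("show", "WtmmSkeleton", function(object) {
  cat(sprintf("WtmmSkeleton: %d lines over %d scales (min span %d)\n",
              nLines(object), length(object@scales), object@minLineScales))
})

setMethod("show", "DetectionGate", function(object) {
  cl <- c(if (!is.na(object@hMax)) sprintf("h <= %g", object@hMax),
          if (!is.na(object@logKMin)) sprintf("logK >= %g", object@logKMin))
  cat("DetectionGate:", paste(cl, collapse = sprintf(" %s ", object@combine)),
      "\n")
})

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult: %d MC lines, %d background lines\n",
              length(object@mcLines), length(object@backgroundLines)))
})

setMethod("show", "PartitionFunctions", function(object) {
  cat(sprintf("PartitionFunctions: %d q values x %d scales, %d-%d lines\n",
              length(object@q), length(object@scales),
              min(object@nLines), max(object@nLines)))
})

setMethod("show", "ScalingExponents", function(object) {
  cat(sprintf("ScalingExponents: q in [%g, %g], tau(0) = %.3f, %d flagged\n",
              min(object@q), max(object@q),
              object@tau[which.min(abs(object@q))], sum(object@flagged)))
})

setMethod("show", "SingularitySpectrum", function(object) {
  cat(sprintf("SingularitySpectrum: D_F = %.3f (curve max %.3f), %d q points\n",
              object@DF, object@DFmax, length(object@q)))
})

setMethod("show", "ZoneGeometry", function(object) {
  cat(sprintf("ZoneGeometry: square [%g, %g]^2, apexes at %g and %g\n",
              object@lo, object@hi, object@apexLow, object@apexHigh))
})

setMethod("show", "CaseClassification", function(object) {
  cat(sprintf("Case %s: (D_CC, D_MLO) = (%.3f, %.3f) -> %s%s\n",
              object@caseId, object@dCC, object@dMLO, object@zone,
              ifelse(is.na(object@subtype), "",
                     paste0(" / ", object@subtype))))
})

setMethod("show", "BetaSpec", function(object) {
  cat(sprintf("Beta(%.5f, %.5f): mean %.4f, sd %.4f\n",
              object@alpha, object@beta, betaMean(object), betaSd(object)))
})

setMethod("show", "HdiInterval", function(object) {
  cat(sprintf("%.0f%% HDI: [%.4f, %.4f]\n", 100 * object@mass,
              object@lower, object@upper))
})

setMethod("show", "PredictiveResult", function(object) {
  cat(sprintf(
    "PredictiveResult: P(k <= %d | n = %d) = %.4f (%d draws, seed %d)\n",
    object@kObs, object@nTrials, object@tailProb, object@nIter, object@seed))
})
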