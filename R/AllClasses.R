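#' @import methods
#' @importFrom stats fft rnorm runif rbeta rbinom qbeta pbeta dbeta optimize
#' @importFrom utils head tail write.csv
NULL

#' Grayscale image container
#'
#' A minimal matrix-backed container for a single-channel image. Rows are
#' image rows (y, downward), columns are image columns (x, rightward); all
#' public pixel coordinates in this package are 0-based, with `x` along
#' columns and `y` along rows. Intensities are finite doubles, conventionally
#' in `[0, 1]` when read from a file. `bitDepth` records the provenance of
#' file-backed images (8 or 16) and is `NA` for synthetic fields.
#'
#' @slot bitDepth integer; source bit depth (8L, 16L or NA).
#' @export
setClass("GrayImage",
  contains = "matrix",
  representation(bitDepth = "integer"),
  prototype(bitDepth = NA_integer_))

setValidity("GrayImage", function(object) {
  if (!is.numeric(object@.Data)) return("pixel values must be numeric")
  if (any(!is.finite(object@.Data))) return("pixel values must all be finite")
  if (!object@bitDepth %in% c(NA_integer_, 8L, 16L))
    return("bitDepth must be 8, 16 or NA")
  TRUE
})

#' Construct a GrayImage
#'
#' @param values numeric matrix of finite intensities (rows = y, cols = x).
#' @param bitDepth 8, 16 or NA (synthetic / unknown provenance).
#' @return a [GrayImage-class] object.
#' @examples
#' img <- GrayImage(matrix(0, 64, 64))
#' dim(img)
#' @export
GrayImage <- function(values, bitDepth = NA_integer_) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("GrayImage", values, bitDepth = as.integer(bitDepth))
}

#' Multiscale gradient-of-Gaussian response
#'
#' Holds, for each analysing scale `a`, the modulus and argument fields of
#' the gradient-of-Gaussian wavelet transform of an image, together with the
#' per-scale border margin (pixels next to the image border that must be
#' ignored because the analysing kernel leaks across the boundary).
#'
#' @slot scales numeric; strictly increasing scales in pixels.
#' @slot modulus list of matrices, one per scale; nonnegative.
#' @slot argument list of matrices, one per scale; values in (-pi, pi].
#' @slot borderMargin integer; `ceiling(3 * a)` per scale.
#' @slot imageDim integer(2); rows, cols of the analysed image.
#' @slot imageMax numeric; largest absolute pixel value (noise-floor scale).
#' @export
setClass("ScaleSpace",
  representation(scales = "numeric", modulus = "list", argument = "list",
                 borderMargin = "integer", imageDim = "integer",
                 imageMax = "numeric"))

setValidity("ScaleSpace", function(object) {
  n <- length(object@scales)
  if (length(object@modulus) != n || length(object@argument) != n)
    return("one modulus and one argument field per scale required")
  if (n > 1 && any(diff(object@scales) <= 0))
    return("scales must be strictly increasing")
  TRUE
})

#' Space-scale skeleton of WTMMM lines
#'
#' The skeleton is the set of vertical space-scale lines obtained by linking
#' the local maxima along maxima chains (WTMMM) across consecutive scales.
#' Samples are stored long-format, one row per (line, scale); each line has
#' exactly one sample per scale inside its span and its anchor is its
#' smallest-scale position.
#'
#' @slot samples data.frame with columns `line`, `scaleIdx`, `scale`, `x`,
#'   `y`, `modulus`.
#' @slot scales numeric; the full analysing scale grid.
#' @slot minLineScales integer; minimum number of consecutive scales a line
#'   must span to be retained.
#' @slot imageDim integer(2).
#' @export
setClass("WtmmSkeleton",
  representation(samples = "data.frame", scales = "numeric",
                 minLineScales = "integer", imageDim = "integer"))

setValidity("WtmmSkeleton", function(object) {
  need <- c("line", "scaleIdx", "scale", "x", "y", "modulus")
  if (!all(need %in% names(object@samples)))
    return(paste("samples must have columns:", paste(need, collapse = ", ")))
  TRUE
})

#' Threshold gate separating microcalcification from background lines
#'
#' A skeleton line with power-law fit `(h, logK)` is called a
#' microcalcification (MC) line when the gate predicate holds. Thresholds may
#' be disabled with `NA`; at least one must be enabled.
#'
#' @slot hMax numeric; line is MC-like when `h <= hMax` (NA disables).
#' @slot logKMin numeric; line is MC-like when `logK >= logKMin` (NA disables).
#' @slot combine "OR" or "AND"; how the two enabled clauses combine.
#' @export
setClass("DetectionGate",
  representation(hMax = "numeric", logKMin = "numeric", combine = "character"),
  prototype(hMax = 0, logKMin = NA_real_, combine = "OR"))

setValidity("DetectionGate", function(object) {
  if (is.na(object@hMax) && is.na(object@logKMin))
    return("at least one of hMax, logKMin must be enabled")
  if (!object@combine %in% c("OR", "AND"))
    return("combine must be 'OR' or 'AND'")
  TRUE
})

#' Construct a detection gate
#'
#' @param hMax Hoelder threshold; a line is MC-like when `h <= hMax`.
#'   `NA` disables the clause. Default 0: discontinuity-like and Dirac-like
#'   singularities have `h <= 0` while rough tissue texture has `h > 0`.
#' @param logKMin prefactor threshold (base-2 log); `NA` (default) disables.
#' @param combine `"OR"` (default) or `"AND"`.
#' @return a [DetectionGate-class].
#' @export
detectionGate <- function(hMax = 0, logKMin = NA_real_, combine = "OR") {
  new("DetectionGate", hMax = as.numeric(hMax), logKMin = as.numeric(logKMin),
      combine = combine)
}

#' Partition of classifiable skeleton lines
#'
#' @slot mcLines integer; ids of microcalcification-class lines.
#' @slot backgroundLines integer; ids of background-tissue lines.
#' @slot gate the [DetectionGate-class] used.
#' @slot fits data.frame of per-line fits used for the decision.
#' @export
setClass("DetectionResult",
  representation(mcLines = "integer", backgroundLines = "integer",
                 gate = "DetectionGate", fits = "data.frame"))

setValidity("DetectionResult", function(object) {
  if (length(intersect(object@mcLines, object@backgroundLines)) > 0)
    return("mcLines and backgroundLines must be disjoint")
  TRUE
})

#' Canonical partition functions over the skeleton
#'
#' For each statistical moment `q` and scale `a`: the log partition function
#' `log Z(q, a)` (natural log) over the sup-modulus of the lines existing at
#' `a`, and the Boltzmann-weighted expectations `h(q, a)` (mean log
#' sup-modulus) and `D(q, a)` (weight entropy), whose slopes against `log a`
#' give the singularity-spectrum coordinates.
#'
#' @slot q numeric moment grid (contains 0).
#' @slot scales numeric scales with at least one contributing line.
#' @slot logZ matrix `length(q) x length(scales)`, natural log of Z.
#' @slot hqa matrix; weighted mean of `log(sup modulus)`.
#' @slot dqa matrix; `sum(W * log W)`.
#' @slot nLines integer; number of contributing lines per scale.
#' @export
setClass("PartitionFunctions",
  representation(q = "numeric", scales = "numeric", logZ = "matrix",
                 hqa = "matrix", dqa = "matrix", nLines = "integer"))

#' Fitted multifractal scaling exponents
#'
#' @slot q numeric moment grid.
#' @slot tau numeric; slope of `log Z(q, a)` vs `log a`.
#' @slot hq numeric; slope of `h(q, a)` vs `log a`.
#' @slot dq numeric; slope of `D(q, a)` vs `log a`.
#' @slot r2 numeric; coefficient of determination of the tau fit per q.
#' @slot flagged logical; q entries with unacceptable fit quality.
#' @slot fitRange numeric(2); scale range (pixels) used for the fits.
#' @export
setClass("ScalingExponents",
  representation(q = "numeric", tau = "numeric", hq = "numeric",
                 dq = "numeric", r2 = "numeric", flagged = "logical",
                 fitRange = "numeric"))

#' Singularity spectrum D(h)
#'
#' The parametric curve `(h(q), D(q))` together with the support dimension
#' `DF = D(q = 0)`, the fractal dimension of the support of singularities.
#' `DFmax` is the numerical maximum over the curve, reported as a diagnostic
#' of how far the parametric reading at q = 0 sits from the curve maximum.
#'
#' @slot q,h,D numeric; unflagged moment grid and curve coordinates.
#' @slot DF numeric; support dimension, `D` at `q = 0`.
#' @slot DFmax numeric; max of `D` over the unflagged curve.
#' @slot legendreGap numeric; per-q residual `D - (q*h - tau)`.
#' @export
setClass("SingularitySpectrum",
  representation(q = "numeric", h = "numeric", D = "numeric", DF = "numeric",
                 DFmax = "numeric", legendreGap = "numeric"))

setValidity("SingularitySpectrum", function(object) {
  # loose sanity bound; estimates fluctuate around the geometric range
  # [0, 2], and zone classification separately enforces its own domain
  if (is.finite(object@DF) && (object@DF < -0.25 || object@DF > 2.5))
    return("support dimension far outside the plausible [0, 2] range")
  TRUE
})

#' Fractal-zone geometry of the CC-MLO plane
#'
#' The fractal zone is a central square plus four triangles, one on each
#' square edge, whose apexes sit on the Euclidean dimensions: as one view's
#' dimension approaches the fractal center the other view's may stray
#' farther, with a linearly decaying allowance that vanishes exactly at
#' D = 1 and D = 2.
#'
#' @slot lo,hi numeric; square bounds (defaults 1.2, 1.8).
#' @slot apexLow,apexHigh numeric; triangle apex ordinates (defaults 1, 2).
#' @export
setClass("ZoneGeometry",
  representation(lo = "numeric", hi = "numeric",
                 apexLow = "numeric", apexHigh = "numeric"),
  prototype(lo = 1.2, hi = 1.8, apexLow = 1, apexHigh = 2))

setValidity("ZoneGeometry", function(object) {
  if (object@apexLow >= object@lo || object@hi >= object@apexHigh)
    return("apexes must lie strictly outside the square")
  if (object@lo >= object@hi) return("square bounds out of order")
  TRUE
})

#' Construct a fractal-zone geometry
#'
#' @param lo,hi bounds of the central square (defaults 1.2 and 1.8).
#' @param apexLow,apexHigh ordinates of the triangle apexes (defaults 1, 2).
#' @return a [ZoneGeometry-class].
#' @export
zoneGeometry <- function(lo = 1.2, hi = 1.8, apexLow = 1, apexHigh = 2) {
  new("ZoneGeometry", lo = lo, hi = hi, apexLow = apexLow, apexHigh = apexHigh)
}

#' Two-view case classification
#'
#' @slot caseId character id.
#' @slot dCC,dMLO numeric; per-view support dimensions (NA if undefined).
#' @slot zone "FRACTAL", "EUCLIDEAN" or "indeterminate".
#' @slot region square / triangle / outside label.
#' @slot subtype "LINE", "SHEET" or NA (fractal or indeterminate cases).
#' @export
setClass("CaseClassification",
  representation(caseId = "character", dCC = "numeric", dMLO = "numeric",
                 zone = "character", region = "character",
                 subtype = "character"))

#' Beta distribution specification
#'
#' @slot alpha,beta positive shape parameters.
#' @export
setClass("BetaSpec", representation(alpha = "numeric", beta = "numeric"))

setValidity("BetaSpec", function(object) {
  if (object@alpha <= 0 || object@beta <= 0)
    return("alpha and beta must be positive")
  TRUE
})

#' Construct a BetaSpec
#'
#' @param alpha,beta positive shape parameters.
#' @return a [BetaSpec-class].
#' @export
betaSpec <- function(alpha, beta) new("BetaSpec", alpha = alpha, beta = beta)

#' Highest density interval
#'
#' @slot lower,upper interval endpoints in `[0, 1]`.
#' @slot mass posterior mass contained.
#' @export
setClass("HdiInterval",
  representation(lower = "numeric", upper = "numeric", mass = "numeric"))

setValidity("HdiInterval", function(object) {
  if (object@lower >= object@upper) return("lower must be below upper")
  if (object@lower < 0 || object@upper > 1) return("endpoints outside [0, 1]")
  TRUE
})

#' Posterior-predictive simulation result
#'
#' @slot k integer; support 0..n of the predictive histogram.
#' @slot freq numeric; relative frequencies (sum to 1).
#' @slot tailProb numeric; fraction of draws with `k <= kObs`.
#' @slot kObs,nTrials,nIter integers; simulation setup.
#' @slot seed integer seed used.
#' @export
setClass("PredictiveResult",
  representation(k = "integer", freq = "numeric", tailProb = "numeric",
                 kObs = "integer", nTrials = "integer", nIter = "integer",
                 seed = "integer"))
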