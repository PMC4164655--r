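# End-to-end region-of-interest and two-view case analysis.

#' Analyse one region of interest
#'
#' Runs the full single-view pipeline: scale space, maxima chains and
#' WTMMM, skeleton, per-line power-law fits (sup-regularized for gating),
#' gate classification, and the singularity spectrum of the
#' microcalcification-line subset. The spectrum's line subset applies the
#' gate without requiring lines to reach the finest scale, so the per-scale
#' census over the detected structures stays complete; reported MC anchors
#' come from the finest-reaching subset. When the MC subset is too small
#' for a spectrum the support dimension is reported as NA rather than
#' failing.
#'
#' @param image a [GrayImage-class] (or matrix), at least 64 x 64.
#' @param gate a [DetectionGate-class]; default `detectionGate()`.
#' @param scaleGrid analysing scales; default [defaultScaleGrid()].
#' @param q moment grid; default [defaultQGrid()].
#' @param fitRange per-line fit range; default in [fitLineScaling()].
#' @param minLineScales minimum skeleton-line span (default 3: long enough
#'   to fit, short enough that the spectrum's line census is not censored).
#' @param minMcLines smallest MC subset for which a spectrum is attempted
#'   (default 8).
#' @param verbose log thresholds and counts with `message()`.
#' @return list with elements `skeleton`, `fits` (regularized), `rawFits`,
#'   `detection`, `spectrum` (NULL when undefined), `DF`, `counts` and
#'   `params`.
#' @export
runRoiAnalysis <- function(image, gate = detectionGate(),
                           scaleGrid = NULL, q = defaultQGrid(),
                           fitRange = NULL, minLineScales = 3L,
                           minMcLines = 8L, verbose = FALSE) {
  if (!is(image, "GrayImage")) image <- GrayImage(image)
  if (is.null(scaleGrid)) scaleGrid <- defaultScaleGrid(image)
  say <- function(...) if (verbose) message(sprintf(...))
  say("scale space: %d scales in [%.2f, %.2f] px", length(scaleGrid),
      min(scaleGrid), max(scaleGrid))
  ss <- computeScaleSpace(image, scaleGrid)
  skel <- computeSkeleton(ss, minLineScales = minLineScales)
  fits <- fitLineScaling(skel, fitRange = fitRange, regularized = TRUE)
  rawFits <- fitLineScaling(skel, fitRange = fitRange)
  say("skeleton: %d lines (min span %d)", nLines(skel), minLineScales)
  det <- classifySkeletonLines(fits, gate)
  say("gate (hMax=%g, logKMin=%g, %s): %d MC lines, %d background lines",
      gate@hMax, gate@logKMin, gate@combine,
      length(det@mcLines), length(det@backgroundLines))
  spec_det <- classifySkeletonLines(fits, gate, requireFinest = FALSE)
  spectrum <- NULL
  DF <- NA_real_
  if (length(spec_det@mcLines) >= minMcLines) {
    pf <- suppressWarnings(
      computePartitionFunctions(skel, lines = spec_det@mcLines, q = q))
    se <- fitScalingExponents(pf)
    spectrum <- tryCatch(singularitySpectrum(se), error = function(e) NULL)
    if (!is.null(spectrum)) DF <- spectrum@DF
  }
  say("support dimension D_F = %s",
      ifelse(is.finite(DF), sprintf("%.3f", DF), "undefined"))
  list(skeleton = skel, fits = fits, rawFits = rawFits, detection = det,
       spectrum = spectrum, DF = DF,
       counts = c(lines = nLines(skel), mc = length(det@mcLines),
                  background = length(det@backgroundLines)),
       params = list(scales = scaleGrid, q = q,
                     gate = c(hMax = gate@hMax, logKMin = gate@logKMin),
                     combine = gate@combine,
                     minLineScales = as.integer(minLineScales),
                     fitRange = fitRange))
}

#' Analyse a two-view case
#'
#' Runs [runRoiAnalysis()] on the CC and MLO views and combines the two
#' support dimensions into the fractal-zone verdict. Views may be given as
#' images or file paths. Optionally writes a JSON report and per-view line
#' feature CSVs.
#'
#' @param cc,mlo the two views: [GrayImage-class] objects or image paths.
#' @param caseId character id for the report.
#' @param gate,scaleGrid,q,fitRange,minLineScales,minMcLines as in
#'   [runRoiAnalysis()].
#' @param geometry a [ZoneGeometry-class].
#' @param outDir optional output directory for `report.json` and the
#'   per-view CSV tables.
#' @return list with `classification` (a [CaseClassification-class]),
#'   `cc` and `mlo` (per-view results).
#' @export
runCaseAnalysis <- function(cc, mlo, caseId = "case",
                            gate = detectionGate(), scaleGrid = NULL,
                            q = defaultQGrid(), fitRange = NULL,
                            minLineScales = 3L, minMcLines = 8L,
                            geometry = zoneGeometry(), outDir = NULL) {
  if (missing(cc) || missing(mlo) || is.null(cc) || is.null(mlo))
    stop("both CC and MLO views are required")
  load1 <- function(v) if (is.character(v)) readGrayImage(v) else v
  resCC <- runRoiAnalysis(load1(cc), gate, scaleGrid, q, fitRange,
                          minLineScales, minMcLines)
  resMLO <- runRoiAnalysis(load1(mlo), gate, scaleGrid, q, fitRange,
                           minLineScales, minMcLines)
  cls <- caseReport(resCC$spectrum, resMLO$spectrum, geometry, caseId)
  # caseReport needs spectra; undefined views must still yield a verdict
  if (is.null(resCC$spectrum) || is.null(resMLO$spectrum))
    cls <- new("CaseClassification", caseId = caseId,
               dCC = resCC$DF, dMLO = resMLO$DF, zone = "indeterminate",
               region = NA_character_, subtype = NA_character_)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeLineFits(resCC$fits, file.path(outDir, "cc_lines.csv"))
    writeLineFits(resMLO$fits, file.path(outDir, "mlo_lines.csv"))
    report <- list(
      case_id = caseId,
      D_cc = resCC$DF, D_mlo = resMLO$DF,
      zone = cls@zone, region = cls@region, subtype = cls@subtype,
      gate = list(h_max = gate@hMax, logK_min = gate@logKMin,
                  combine = gate@combine),
      counts = list(cc = as.list(resCC$counts),
                    mlo = as.list(resMLO$counts)),
      params = list(n_scales = length(resCC$params$scales),
                    a_min = min(resCC$params$scales),
                    a_max = max(resCC$params$scales),
                    q_min = min(q), q_max = max(q)),
      metadata = list(tool = "mcfractal",
                      version = as.character(utils::packageVersion("mcfractal")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(classification = cls, cc = resCC, mlo = resMLO)
}
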