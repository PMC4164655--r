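# Partition of skeleton lines into microcalcification vs background classes.

#' Classify skeleton lines with an (h, logK) threshold gate
#'
#' Applies the gate predicate to each classifiable line: a line is
#' microcalcification-class (MC) when `h <= hMax` and/or `logK >= logKMin`,
#' according to the enabled clauses and their combination. With
#' `requireFinest = TRUE` (default) classifiable lines are those with a
#' finite power-law fit that also reach the finest grid scale — the right
#' population when MC anchors must localize singularities in the
#' small-scale limit. Set it to FALSE when selecting the line subset for a
#' singularity spectrum: lines born at coarser scales over the same
#' structures keep the per-scale line census complete.
#'
#' @param fits data.frame from [fitLineScaling()].
#' @param gate a [DetectionGate-class]; default `detectionGate()` (h <= 0).
#' @param requireFinest restrict to lines reaching the finest scale.
#' @return a [DetectionResult-class].
#' @examples
#' fits <- data.frame(line = 1:3, h = c(-0.5, 0.4, 0.7),
#'                    logK = c(5, 1, 0), reachesFinest = TRUE)
#' mcLines(classifySkeletonLines(fits))
#' @export
classifySkeletonLines <- function(fits, gate = detectionGate(),
                                  requireFinest = TRUE) {
  validObject(gate)
  cl <- fits[is.finite(fits$h) & is.finite(fits$logK), , drop = FALSE]
  if (requireFinest && "reachesFinest" %in% names(cl))
    cl <- cl[cl$reachesFinest, , drop = FALSE]
  if (nrow(cl) == 0) stop("no classifiable skeleton lines")
  clauses <- list()
  if (!is.na(gate@hMax)) clauses$h <- cl$h <= gate@hMax
  if (!is.na(gate@logKMin)) clauses$k <- cl$logK >= gate@logKMin
  isMC <- if (length(clauses) == 1) clauses[[1]]
          else if (gate@combine == "OR") clauses$h | clauses$k
          else clauses$h & clauses$k
  new("DetectionResult",
      mcLines = as.integer(cl$line[isMC]),
      backgroundLines = as.integer(cl$line[!isMC]),
      gate = gate, fits = cl)
}

#' Render binary chain masks for the two line classes
#'
#' Two masks at the finest scale and the input image's dimensions: pixels of
#' maxima chains whose chain carries an MC-class anchor, and pixels of the
#' remaining chains. The masks are disjoint by construction.
#'
#' @param result a [DetectionResult-class].
#' @param skeleton the [WtmmSkeleton-class] the result came from.
#' @param ss the [ScaleSpace-class] of the analysed image.
#' @return list with integer matrices `mcMask` and `backgroundMask` (0/1).
#' @export
renderOverlay <- function(result, skeleton, ss) {
  dm <- ss@imageDim
  mc <- matrix(0L, dm[1], dm[2]); bg <- matrix(0L, dm[1], dm[2])
  chains <- extractMaximaChains(ss, 1, ordered = FALSE)
  if (nrow(chains)) {
    a1 <- anchors(skeleton)
    a1 <- a1[a1$scale == ss@scales[1], , drop = FALSE]
    # a chain is MC-class when an MC anchor lies on it
    key <- chains$x * (dm[1] + 2) + chains$y
    anchorChain <- chains$chain[match(a1$x * (dm[1] + 2) + a1$y, key)]
    mcChains <- unique(anchorChain[a1$line %in% result@mcLines])
    mcChains <- mcChains[!is.na(mcChains)]
    sel <- chains$chain %in% mcChains
    mc[cbind(chains$y[sel] + 1, chains$x[sel] + 1)] <- 1L
    bg[cbind(chains$y[!sel] + 1, chains$x[!sel] + 1)] <- 1L
  }
  list(mcMask = mc, backgroundMask = bg)
}
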