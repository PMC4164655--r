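# The CC-MLO fractal dimension plot: fractal zone membership and Euclidean
# LINE/SHEET subtyping of two-view cases.

triangleHalfWidth <- function(d, g) {
  # half-width of the vertical triangles at ordinate d (0 outside)
  half <- (g@hi - g@lo) / 2
  ifelse(d >= g@apexLow & d < g@lo,
         half * (d - g@apexLow) / (g@lo - g@apexLow),
  ifelse(d > g@hi & d <= g@apexHigh,
         half * (g@apexHigh - d) / (g@apexHigh - g@hi), 0))
}

#' Fractal-zone membership of a two-view dimension pair
#'
#' Point-in-region test on the closed union of the central square and the
#' four triangles (boundaries count as inside). The region label records
#' which component contains the point.
#'
#' @param dCC,dMLO per-view support dimensions, each in `[0, 2.1]`.
#' @param geometry a [ZoneGeometry-class]; default `zoneGeometry()`.
#' @return list with elements `zone` ("FRACTAL" or "EUCLIDEAN") and
#'   `region` ("square", "bottom"/"top"/"left"/"right" triangle, or
#'   "outside").
#' @examples
#' zoneMembership(1.5, 1.5)$zone    # FRACTAL (square)
#' zoneMembership(1.19, 1.19)$zone  # EUCLIDEAN
#' @export
zoneMembership <- function(dCC, dMLO, geometry = zoneGeometry()) {
  g <- geometry
  if (dCC < 0 || dCC > 2.1 || dMLO < 0 || dMLO > 2.1)
    stop("dimensions must lie in [0, 2.1]")
  ctr <- (g@lo + g@hi) / 2
  region <- "outside"
  if (dCC >= g@lo && dCC <= g@hi && dMLO >= g@lo && dMLO <= g@hi) {
    region <- "square"
  } else if (abs(dCC - ctr) <= triangleHalfWidth(dMLO, g)) {
    region <- if (dMLO < g@lo) "bottom" else "top"
  } else if (abs(dMLO - ctr) <= triangleHalfWidth(dCC, g)) {
    region <- if (dCC < g@lo) "left" else "right"
  }
  list(zone = if (region == "outside") "EUCLIDEAN" else "FRACTAL",
       region = region)
}

#' Euclidean LINE/SHEET subtype of a non-fractal case
#'
#' Rounds each view's dimension to the nearer of the Euclidean values 1 and
#' 2 (exact midpoints resolve to 1). LINE when both views round to 1 (a
#' one-dimensional object from both views); SHEET otherwise (a full
#' two-dimensional object in at least one view).
#'
#' @param dCC,dMLO per-view support dimensions.
#' @param geometry a [ZoneGeometry-class] used to verify the contract.
#' @return "LINE" or "SHEET".
#' @examples
#' euclideanSubtype(1.0, 1.0)  # LINE
#' euclideanSubtype(1.0, 2.0)  # SHEET
#' @export
euclideanSubtype <- function(dCC, dMLO, geometry = zoneGeometry()) {
  if (zoneMembership(dCC, dMLO, geometry)$zone != "EUCLIDEAN")
    stop("subtype is defined only for EUCLIDEAN verdicts")
  nearer <- function(d) if (abs(d - 1) <= abs(d - 2)) 1 else 2
  if (nearer(dCC) == 1 && nearer(dMLO) == 1) "LINE" else "SHEET"
}

#' Assemble a two-view case classification
#'
#' Combines the per-view support dimensions into a fractal-zone verdict and,
#' for Euclidean cases, the LINE/SHEET subtype. Either dimension being
#' undefined (NA) yields an "indeterminate" verdict.
#'
#' @param ccSpectrum,mloSpectrum [SingularitySpectrum-class] objects from
#'   the MC-line subsets of the two views (or NULL when a view has no MC
#'   subset).
#' @param geometry a [ZoneGeometry-class].
#' @param caseId character id echoed in the result.
#' @return a [CaseClassification-class].
#' @export
caseReport <- function(ccSpectrum, mloSpectrum, geometry = zoneGeometry(),
                       caseId = "case") {
  if (missing(ccSpectrum) || missing(mloSpectrum))
    stop("both views are required")
  d <- function(sp) {
    if (is.null(sp)) return(NA_real_)
    if (!is(sp, "SingularitySpectrum"))
      stop("spectra must be SingularitySpectrum objects")
    sp@DF
  }
  dCC <- d(ccSpectrum); dMLO <- d(mloSpectrum)
  if (!is.finite(dCC) || !is.finite(dMLO))
    return(new("CaseClassification", caseId = caseId, dCC = dCC, dMLO = dMLO,
               zone = "indeterminate", region = NA_character_,
               subtype = NA_character_))
  mem <- zoneMembership(dCC, dMLO, geometry)
  sub <- if (mem$zone == "EUCLIDEAN")
    euclideanSubtype(dCC, dMLO, geometry) else NA_character_
  new("CaseClassification", caseId = caseId, dCC = dCC, dMLO = dMLO,
      zone = mem$zone, region = mem$region, subtype = sub)
}
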