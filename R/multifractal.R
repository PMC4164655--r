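# Canonical multifractal formalism over a skeleton subset: partition
# functions with Boltzmann weights, scaling exponents tau(q), h(q), D(q),
# and the D(h) singularity spectrum with support dimension D_F.

#' Default moment grid
#'
#' `q` from -2 to 4 in steps of 0.25 (contains 0). Larger |q| is unstable
#' when few lines contribute.
#'
#' @return numeric vector of moments.
#' @export
defaultQGrid <- function() seq(-2, 4, by = 0.25)

#' Compute canonical partition functions over a skeleton subset
#'
#' For each scale `a` of the grid, the contributing set `L(a)` holds the
#' lines that exist at `a`; each line contributes the supremum of its
#' modulus over its samples at scales up to `a`. Then
#' `Z(q, a) = sum(sup^q)`, the Boltzmann weights are `W = sup^q / Z(q, a)`,
#' and the weighted expectations are `h(q, a) = sum(W * log(sup))` and
#' `D(q, a) = sum(W * log W)`. All computations run in the log domain so
#' that large |q| does not overflow. Lines with zero supremum are excluded
#' before exponentiation; scales where no line contributes are dropped with
#' a warning.
#'
#' @param skeleton a [WtmmSkeleton-class].
#' @param lines optional integer vector of line ids (default: all lines).
#' @param q moment grid containing 0; default [defaultQGrid()].
#' @return a [PartitionFunctions-class].
#' @export
computePartitionFunctions <- function(skeleton, lines = NULL,
                                      q = defaultQGrid()) {
  if (!any(q == 0)) stop("the moment grid must contain q = 0")
  s <- skeleton@samples
  if (!is.null(lines)) s <- s[s$line %in% lines, , drop = FALSE]
  if (nrow(s) == 0) stop("empty skeleton subset")
  s <- s[order(s$line, s$scaleIdx), ]
  # running supremum of the modulus along each line (scales <= a)
  sup <- ave(s$modulus, s$line, FUN = cummax)
  keep <- sup > 0
  if (!any(keep)) stop("all line suprema are zero")
  s <- s[keep, , drop = FALSE]; sup <- sup[keep]
  lsup <- log(sup)

  scaleIdx <- sort(unique(s$scaleIdx))
  nq <- length(q); na <- length(scaleIdx)
  logZ <- matrix(NA_real_, nq, na)
  hqa <- matrix(NA_real_, nq, na)
  dqa <- matrix(NA_real_, nq, na)
  nLines <- integer(na)
  for (j in seq_len(na)) {
    lv <- lsup[s$scaleIdx == scaleIdx[j]]
    nLines[j] <- length(lv)
    for (k in seq_len(nq)) {
      e <- q[k] * lv
      m <- max(e)
      lz <- m + log(sum(exp(e - m)))
      w <- exp(e - lz)
      logZ[k, j] <- lz
      hqa[k, j] <- sum(w * lv)
      dqa[k, j] <- q[k] * hqa[k, j] - lz   # sum(W * log W)
    }
  }
  dropped <- setdiff(seq_along(skeleton@scales), scaleIdx)
  if (length(dropped))
    warning(sprintf("%d scale(s) without contributing lines dropped",
                    length(dropped)))
  new("PartitionFunctions", q = as.numeric(q),
      scales = skeleton@scales[scaleIdx],
      logZ = logZ, hqa = hqa, dqa = dqa, nLines = nLines)
}

# slope of y against log(a) over selected columns, plus R^2
slopeFit <- function(y, la) {
  n <- length(la)
  vx <- sum((la - mean(la))^2)
  slope <- sum((la - mean(la)) * (y - mean(y))) / vx
  res <- y - mean(y) - slope * (la - mean(la))
  vy <- sum((y - mean(y))^2)
  r2 <- if (vy > 0) 1 - sum(res^2) / vy else 1
  c(slope = slope, r2 = r2)
}

#' Fit the multifractal scaling exponents
#'
#' Per moment `q`: `tau(q)` is the slope of `log Z(q, a)` against `log a`,
#' `h(q)` the slope of the expectation `h(q, a)` and `D(q)` the slope of
#' `D(q, a)`, over the scales inside `fitRange`. Moments whose tau fit has
#' `R^2 < r2Min` are flagged.
#'
#' When no `fitRange` is given, the scaling window is located
#' automatically: among all windows spanning at least `minOctaves` octaves
#' whose fine end is not below the scale where the contributing-line count
#' peaks (finer scales are censored flat by the minimum line span) and
#' whose coarse end still holds at least `minCount` lines, the one with the
#' straightest `log Z(0, a)` vs `log a` relation (highest R^2, ties to the
#' widest) is used. Structured inputs enter their self-similar regime only
#' above the size of their elementary structures and leave it when lines
#' deplete, and neither boundary is known a priori.
#'
#' @param pf a [PartitionFunctions-class].
#' @param fitRange numeric(2), scale range in pixels; NULL for the
#'   automatic window; the string `"census"` for the full census-complete
#'   range (peak of the line count to the last scale with `minCount`
#'   lines), appropriate for space-filling textures with no elementary
#'   structure size.
#' @param minCount smallest line count accepted at the coarse end of the
#'   automatic window (default 5).
#' @param minOctaves minimum width of the automatic window (default 1.25).
#' @param r2Min fit-quality floor for flagging (default 0.9).
#' @return a [ScalingExponents-class].
#' @export
fitScalingExponents <- function(pf, fitRange = NULL, minCount = 5,
                                minOctaves = 1.25, r2Min = 0.9) {
  a <- pf@scales
  loIdx <- max(which(pf@nLines == max(pf@nLines)))
  hiOk <- which(pf@nLines >= minCount)
  hiIdx <- if (length(hiOk)) max(hiOk) else length(a)
  if (identical(fitRange, "census")) {
    fitRange <- if (hiIdx - loIdx >= 2) c(a[loIdx], a[hiIdx]) else range(a)
  } else if (is.null(fitRange)) {
    i0q <- which(pf@q == 0)
    best <- NULL
    if (hiIdx - loIdx >= 2) {
      for (i in loIdx:(hiIdx - 2)) for (j in (i + 2):hiIdx) {
        if (log2(a[j] / a[i]) < minOctaves) next
        ft <- slopeFit(pf@logZ[i0q, i:j], log(a[i:j]))
        w <- log2(a[j] / a[i])
        if (is.null(best) || ft["r2"] > best$r2 + 1e-12 ||
            (abs(ft["r2"] - best$r2) <= 1e-12 && w > best$w)) {
          best <- list(r2 = ft["r2"], w = w, i = i, j = j)
        }
      }
    }
    fitRange <- if (is.null(best)) range(a) else c(a[best$i], a[best$j])
  }
  sel <- which(a >= fitRange[1] & a <= fitRange[2])
  if (length(sel) < 3) sel <- seq_along(a)
  if (length(sel) < 3) stop("need at least 3 scales in the fit range")
  la <- log(a[sel])
  nq <- length(pf@q)
  tau <- hq <- dq <- r2 <- rep(NA_real_, nq)
  for (k in seq_len(nq)) {
    ft <- slopeFit(pf@logZ[k, sel], la)
    tau[k] <- ft["slope"]; r2[k] <- ft["r2"]
    hq[k] <- slopeFit(pf@hqa[k, sel], la)["slope"]
    dq[k] <- slopeFit(pf@dqa[k, sel], la)["slope"]
  }
  new("ScalingExponents", q = pf@q, tau = tau, hq = hq, dq = dq, r2 = r2,
      flagged = !is.finite(tau) | r2 < r2Min,
      fitRange = as.numeric(c(a[sel][1], a[sel][length(sel)])))
}

#' Singularity spectrum from fitted exponents
#'
#' The parametric curve `(h(q), D(q))` over unflagged moments. The support
#' dimension `D_F` is read at `q = 0`, the parametric location of the
#' spectrum maximum; the numerical maximum over the curve is also computed
#' and their difference serves as a diagnostic. The per-q consistency gap
#' `D(q) - (q * h(q) - tau(q))` against the Legendre-transform relation is
#' recorded.
#'
#' @param se a [ScalingExponents-class].
#' @return a [SingularitySpectrum-class].
#' @export
singularitySpectrum <- function(se) {
  i0 <- which(se@q == 0)
  if (length(i0) != 1) stop("q = 0 missing from the moment grid")
  if (se@flagged[i0]) stop("q = 0 fit is flagged; spectrum undefined")
  ok <- !se@flagged
  gap <- se@dq - (se@q * se@hq - se@tau)
  new("SingularitySpectrum", q = se@q[ok], h = se@hq[ok], D = se@dq[ok],
      DF = se@dq[i0], DFmax = max(se@dq[ok]), legendreGap = gap[ok])
}
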