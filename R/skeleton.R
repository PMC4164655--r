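# Maxima chains, WTMMM and the space-scale skeleton.

# vectorized bilinear interpolation of matrix M at 0-based (xq, yq)
bilinearAt <- function(M, xq, yq) {
  nr <- nrow(M); nc <- ncol(M)
  xf <- pmin(pmax(floor(xq), 0), nc - 2)
  yf <- pmin(pmax(floor(yq), 0), nr - 2)
  fx <- xq - xf; fy <- yq - yf
  i <- yf + 1; j <- xf + 1
  M[cbind(i, j)] * (1 - fx) * (1 - fy) +
    M[cbind(i, j + 1)] * fx * (1 - fy) +
    M[cbind(i + 1, j)] * (1 - fx) * fy +
    M[cbind(i + 1, j + 1)] * fx * fy
}

# order the points of one connected chain by a greedy adjacency walk,
# starting from an endpoint when one exists (closed chains start anywhere);
# at a dead end the walk re-enters at an unvisited point next to the
# visited set, so only locally thick chain knots can break adjacency
orderChainPoints <- function(members, adj) {
  deg <- lengths(adj[members])
  start <- if (any(deg == 1)) members[deg == 1][1] else members[1]
  seen <- logical(max(members))
  visited <- integer(length(members))
  v <- start
  for (k in seq_along(members)) {
    visited[k] <- v
    seen[v] <- TRUE
    if (k == length(members)) break
    nb <- adj[[v]]
    nxt <- nb[!seen[nb]]
    if (length(nxt)) {
      # prefer continuing along the thin chain over entering a knot
      v <- nxt[which.min(lengths(adj[nxt]))]
    } else {
      rest <- members[!seen[members]]
      touch <- rest[vapply(rest, function(u) any(seen[adj[[u]]]),
                           logical(1))]
      v <- if (length(touch)) touch[1] else rest[1]
    }
  }
  visited
}

#' Extract maxima chains at one scale
#'
#' A pixel belongs to the wavelet-transform modulus maxima (WTMM) set when
#' its modulus is at least both bilinearly interpolated moduli one pixel
#' away along the local gradient direction (and strictly larger on at least
#' one side). WTMM pixels are grouped into chains by 8-connectivity; chains
#' shorter than 3 pixels, and chains entering the per-scale border margin,
#' are discarded.
#'
#' @param ss a [ScaleSpace-class].
#' @param i scale index into `scales(ss)`.
#' @param ordered logical; when TRUE (default) points of each chain are
#'   returned in traversal order along the chain (slower); when FALSE the
#'   within-chain order is unspecified.
#' @return data.frame with columns `chain`, `x`, `y` (0-based pixel
#'   coordinates), `modulus`, `argument`; attributes `scale` and `imageDim`.
#' @export
extractMaximaChains <- function(ss, i, ordered = TRUE) {
  if (i < 1 || i > length(ss@scales)) stop("scale index outside the grid")
  M <- ss@modulus[[i]]; A <- ss@argument[[i]]
  nr <- nrow(M); nc <- ncol(M)
  ux <- cos(A); uy <- sin(A)
  X <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  Y <- matrix(seq_len(nr) - 1, nr, nc)
  xf <- X + ux; yf <- Y + uy
  xb <- X - ux; yb <- Y - uy
  ok <- xf >= 0 & xf <= nc - 1 & yf >= 0 & yf <= nr - 1 &
        xb >= 0 & xb <= nc - 1 & yb >= 0 & yb <= nr - 1
  Mf <- matrix(Inf, nr, nc); Mb <- matrix(Inf, nr, nc)
  Mf[ok] <- bilinearAt(M, xf[ok], yf[ok])
  Mb[ok] <- bilinearAt(M, xb[ok], yb[ok])
  # a WTMM pixel must dominate both probes and show genuine peak curvature:
  # the curvature floor rejects roundoff-scale ripples of flat or monotone
  # modulus fields (constant and ramp images, padding leakage) while
  # keeping even weak real maxima, whose curvature is orders above it
  tol <- 1e-7 * max(M)
  # fields that are pure roundoff (e.g. a constant image) carry no maxima
  significant <- max(M) > 1e-10 * ss@imageMax * ss@scales[i]
  mask <- significant & ok & M > 0 & M >= Mf & M >= Mb &
          (2 * M - Mf - Mb > tol)
  # maxima inside the border margin are contaminated by the padding
  marg <- ss@borderMargin[i]
  if (2 * marg >= min(nr, nc)) mask[] <- FALSE else {
    mask[c(seq_len(marg), nr - seq_len(marg) + 1L), ] <- FALSE
    mask[, c(seq_len(marg), nc - seq_len(marg) + 1L)] <- FALSE
  }

  empty <- data.frame(chain = integer(), x = numeric(), y = numeric(),
                      modulus = numeric(), argument = numeric())
  attr(empty, "scale") <- ss@scales[i]
  attr(empty, "imageDim") <- c(nr, nc)
  if (!any(mask)) return(empty)

  idx <- which(mask)                         # column-major linear indices
  rank <- integer(nr * nc); rank[idx] <- seq_along(idx)
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    dr <- off[1]; dc <- off[2]
    r0 <- max(1L, 1L - dr):min(nr, nr - dr)
    c0 <- max(1L, 1L - dc):min(nc, nc - dc)
    both <- mask[r0, c0, drop = FALSE] & mask[r0 + dr, c0 + dc, drop = FALSE]
    if (!any(both)) next
    w <- which(both)
    rr <- r0[(w - 1L) %% length(r0) + 1L]
    cc <- c0[(w - 1L) %/% length(r0) + 1L]
    e1 <- rank[(cc - 1L) * nr + rr]
    e2 <- rank[(cc + dc - 1L) * nr + rr + dr]
    edges <- rbind(edges, cbind(e1, e2))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)

  px <- (idx - 1L) %/% nr            # 0-based x (column)
  py <- (idx - 1L) %% nr             # 0-based y (row)
  keep <- which(sizes >= 3)
  if (length(keep) == 0) return(empty)

  sel <- memb %in% keep
  ord <- seq_along(idx)[sel]
  if (ordered) {
    adj <- vector("list", length(idx))
    if (!is.null(edges)) {
      el <- rbind(edges, edges[, 2:1, drop = FALSE])
      adj <- unname(split(el[, 2], factor(el[, 1], levels = seq_along(idx))))
    }
    ord <- unlist(lapply(keep, function(k)
      orderChainPoints(which(memb == k), adj)), use.names = FALSE)
  }
  out <- data.frame(
    chain = match(memb[ord], keep),
    x = px[ord], y = py[ord],
    modulus = M[idx[ord]], argument = A[idx[ord]])
  attr(out, "scale") <- ss@scales[i]
  attr(out, "imageDim") <- c(nr, nc)
  out
}

#' Locate the modulus maxima along maxima chains (WTMMM)
#'
#' A chain point is a WTMMM when its modulus is at least that of all its
#' chain neighbors (the 8-adjacent points of the same chain; for closed
#' chains the neighborhood wraps around by construction). Runs of adjacent
#' tied candidates collapse to a single point: the largest modulus, ties
#' broken by the smallest `(y, x)` position.
#'
#' @param chains data.frame from [extractMaximaChains()] (one scale).
#' @return data.frame with columns `chain`, `x`, `y`, `modulus`; attribute
#'   `scale` carried over.
#' @export
locateWtmmm <- function(chains) {
  empty <- data.frame(chain = integer(), x = numeric(), y = numeric(),
                      modulus = numeric())
  attr(empty, "scale") <- attr(chains, "scale")
  if (nrow(chains) == 0) return(empty)
  dm <- attr(chains, "imageDim")
  nr <- if (!is.null(dm)) dm[1] else max(chains$y) + 2
  key <- chains$x * (nr + 2) + chains$y          # unique integer per pixel
  lookup <- match(key, key)                      # identity; used via match()
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  nbMax <- rep(-Inf, nrow(chains))
  nbEdges <- NULL
  for (r in seq_len(nrow(offs))) {
    j <- match((chains$x + offs$dx[r]) * (nr + 2) + (chains$y + offs$dy[r]),
               key)
    hit <- which(!is.na(j) & chains$chain[j] == chains$chain)
    if (!length(hit)) next
    nbMax[hit] <- pmax(nbMax[hit], chains$modulus[j[hit]])
    nbEdges <- rbind(nbEdges, cbind(hit, j[hit]))
  }
  cand <- which(is.finite(nbMax) & chains$modulus >= nbMax)
  if (!length(cand)) return(empty)
  # collapse adjacent candidate runs (plateaus) to one representative
  sub <- nbEdges[nbEdges[, 1] %in% cand & nbEdges[, 2] %in% cand, ,
                 drop = FALSE]
  g <- igraph::make_empty_graph(n = length(cand), directed = FALSE)
  if (nrow(sub))
    g <- igraph::add_edges(g, t(matrix(match(sub, cand), ncol = 2)))
  memb <- igraph::components(g)$membership
  o <- order(memb, -chains$modulus[cand], chains$y[cand], chains$x[cand])
  first <- o[!duplicated(memb[o])]
  pick <- cand[first]
  out <- data.frame(chain = chains$chain[pick], x = chains$x[pick],
                    y = chains$y[pick], modulus = chains$modulus[pick])
  out <- out[order(out$chain, out$y, out$x), ]
  rownames(out) <- NULL
  attr(out, "scale") <- attr(chains, "scale")
  out
}

#' Link WTMMM across scales into the space-scale skeleton
#'
#' Greedy mutual-nearest-neighbor matching between consecutive scales, fine
#' to coarse: a fine-scale line head and a coarse-scale point are linked when
#' each is the other's nearest neighbor and their distance does not exceed
#' the linking radius (default `max(2, 1.5 * a_coarser)` pixels). Unmatched
#' line heads terminate; unmatched coarse points start new lines at that
#' scale. Lines spanning fewer than `minLineScales` consecutive scales are
#' dropped.
#'
#' @param wtmmmByScale list of data.frames from [locateWtmmm()], one per
#'   scale of `scaleGrid`, fine to coarse.
#' @param scaleGrid numeric vector of scales (pixels).
#' @param linkRadius function of the coarser scale returning the matching
#'   radius in pixels; NULL for the default rule.
#' @param minLineScales minimum line span in scales (default 10).
#' @param imageDim integer(2) rows, cols (for downstream bookkeeping).
#' @return a [WtmmSkeleton-class].
#' @export
buildSkeleton <- function(wtmmmByScale, scaleGrid, linkRadius = NULL,
                          minLineScales = 10L, imageDim = c(NA_integer_,
                                                            NA_integer_)) {
  nS <- length(scaleGrid)
  if (length(wtmmmByScale) != nS)
    stop("need one WTMMM set per scale")
  if (nS < minLineScales)
    stop("scale grid shorter than the minimum line span")
  if (is.null(linkRadius))
    linkRadius <- function(aCoarser) max(2, 1.5 * aCoarser)

  chunks <- vector("list", nS)
  pts1 <- wtmmmByScale[[1]]
  nextId <- nrow(pts1)
  active <- if (nrow(pts1)) data.frame(line = seq_len(nrow(pts1)),
                                       x = pts1$x, y = pts1$y)
            else data.frame(line = integer(), x = numeric(), y = numeric())
  if (nrow(pts1))
    chunks[[1]] <- data.frame(line = active$line, scaleIdx = 1L,
                              scale = scaleGrid[1], x = pts1$x, y = pts1$y,
                              modulus = pts1$modulus)
  for (i in 2:nS) {
    B <- wtmmmByScale[[i]]
    r <- linkRadius(scaleGrid[i])
    nA <- nrow(active); nB <- nrow(B)
    matchA <- integer(0); matchB <- integer(0)
    if (nA > 0 && nB > 0) {
      D <- outer(active$x, B$x, "-")^2 + outer(active$y, B$y, "-")^2
      r2 <- r^2
      freeA <- rep(TRUE, nA); freeB <- rep(TRUE, nB)
      repeat {
        W <- D
        W[!freeA, ] <- Inf; W[, !freeB] <- Inf
        if (all(!is.finite(W))) break
        ja <- max.col(-W, ties.method = "first")
        da <- W[cbind(seq_len(nA), ja)]
        ib <- max.col(-t(W), ties.method = "first")
        mut <- which(freeA & da <= r2 & ib[ja] == seq_len(nA))
        if (!length(mut)) break
        matchA <- c(matchA, mut); matchB <- c(matchB, ja[mut])
        freeA[mut] <- FALSE; freeB[ja[mut]] <- FALSE
      }
    }
    newActive <- list()
    if (length(matchA)) {
      ext <- data.frame(line = active$line[matchA], scaleIdx = i,
                        scale = scaleGrid[i], x = B$x[matchB],
                        y = B$y[matchB], modulus = B$modulus[matchB])
      newActive[[1]] <- data.frame(line = ext$line, x = ext$x, y = ext$y)
      chunks[[i]] <- ext
    }
    unB <- setdiff(seq_len(nB), matchB)
    if (length(unB)) {
      ids <- nextId + seq_along(unB)
      nextId <- nextId + length(unB)
      st <- data.frame(line = ids, scaleIdx = i, scale = scaleGrid[i],
                       x = B$x[unB], y = B$y[unB], modulus = B$modulus[unB])
      newActive[[length(newActive) + 1]] <-
        data.frame(line = ids, x = st$x, y = st$y)
      chunks[[i]] <- rbind(chunks[[i]], st)
    }
    active <- if (length(newActive)) do.call(rbind, newActive)
              else data.frame(line = integer(), x = numeric(), y = numeric())
  }
  samples <- do.call(rbind, chunks[!vapply(chunks, is.null, logical(1))])
  if (is.null(samples) || nrow(samples) == 0) {
    samples <- data.frame(line = integer(), scaleIdx = integer(),
                          scale = numeric(), x = numeric(), y = numeric(),
                          modulus = numeric())
    return(new("WtmmSkeleton", samples = samples,
               scales = as.numeric(scaleGrid),
               minLineScales = as.integer(minLineScales),
               imageDim = as.integer(imageDim)))
  }
  span <- table(samples$line)
  keep <- as.integer(names(span)[span >= minLineScales])
  samples <- samples[samples$line %in% keep, , drop = FALSE]
  samples$line <- match(samples$line, sort(unique(samples$line)))
  samples <- samples[order(samples$line, samples$scaleIdx), , drop = FALSE]
  rownames(samples) <- NULL
  new("WtmmSkeleton", samples = samples, scales = as.numeric(scaleGrid),
      minLineScales = as.integer(minLineScales),
      imageDim = as.integer(imageDim))
}

#' Compute the full skeleton of an image scale space
#'
#' Convenience wrapper: extracts maxima chains and WTMMM at every scale,
#' then links them with [buildSkeleton()].
#'
#' @param ss a [ScaleSpace-class].
#' @param minLineScales,linkRadius passed to [buildSkeleton()].
#' @return a [WtmmSkeleton-class].
#' @export
computeSkeleton <- function(ss, minLineScales = 10L, linkRadius = NULL) {
  wt <- lapply(seq_along(ss@scales), function(i)
    locateWtmmm(extractMaximaChains(ss, i, ordered = FALSE)))
  buildSkeleton(wt, ss@scales, linkRadius = linkRadius,
                minLineScales = minLineScales, imageDim = ss@imageDim)
}

#' Fit the per-line power law modulus ~ K * a^h
#'
#' Ordinary least squares of `log2(modulus)` against `log2(a)` over the fit
#' range, per skeleton line: the slope is the Hoelder exponent `h` and the
#' intercept `log2(K)`. Lines with fewer than 3 samples inside the range get
#' NA fits.
#'
#' With `regularized = TRUE` the fit uses the running supremum of the
#' modulus over the line's samples at scales up to `a` (the same
#' regularization the partition functions use) instead of the raw modulus.
#' The raw modulus along a line drops steeply over the last fraction of an
#' octave before the line annihilates in a merger, whatever the local
#' regularity, which drags raw per-line slopes far below the true Hoelder
#' exponent; the supremum freezes during that decay, so background-texture
#' lines keep `h` near the texture's roughness exponent while lines pointing
#' to bright compact singularities (whose modulus peaks at the smallest
#' scale) get `h = 0` exactly and still satisfy an `h <= 0` gate.
#'
#' @param skeleton a [WtmmSkeleton-class].
#' @param fitRange numeric(2) scale range in pixels; default
#'   `c(min(scales), min(200, max(scales)))`.
#' @param regularized fit the running sup-modulus instead of the raw
#'   modulus (default FALSE).
#' @return data.frame with one row per line: `line`, `h`, `logK`, `nFit`,
#'   `nScales`, `residual` (rms of the fit), `anchorX`, `anchorY`,
#'   `reachesFinest`.
#' @export
fitLineScaling <- function(skeleton, fitRange = NULL, regularized = FALSE) {
  s <- skeleton@samples
  if (nrow(s) == 0)
    return(data.frame(line = integer(), h = numeric(), logK = numeric(),
                      nFit = integer(), nScales = integer(),
                      residual = numeric(), anchorX = numeric(),
                      anchorY = numeric(), reachesFinest = logical()))
  if (is.null(fitRange))
    fitRange <- c(min(skeleton@scales), min(200, max(skeleton@scales)))
  lines <- sort(unique(s$line))
  anch <- anchors(skeleton)
  spans <- tabulate(s$line, nbins = max(lines))[lines]
  minIdx <- tapply(s$scaleIdx, s$line, min)[as.character(lines)]

  if (regularized) {
    s <- s[order(s$line, s$scaleIdx), ]
    s$modulus <- ave(s$modulus, s$line, FUN = cummax)
  }
  f <- s[s$scale >= fitRange[1] & s$scale <= fitRange[2] & s$modulus > 0, ]
  out <- data.frame(line = lines, h = NA_real_, logK = NA_real_,
                    nFit = 0L, nScales = spans, residual = NA_real_,
                    anchorX = anch$x[match(lines, anch$line)],
                    anchorY = anch$y[match(lines, anch$line)],
                    reachesFinest = minIdx == 1L)
  if (nrow(f) == 0) return(out)
  lx <- log2(f$scale); ly <- log2(f$modulus)
  present <- sort(unique(f$line))
  grp <- factor(f$line, levels = present)
  n <- as.numeric(rowsum(rep(1, nrow(f)), grp))
  Sx <- as.numeric(rowsum(lx, grp)); Sy <- as.numeric(rowsum(ly, grp))
  Sxx <- as.numeric(rowsum(lx^2, grp)); Syy <- as.numeric(rowsum(ly^2, grp))
  Sxy <- as.numeric(rowsum(lx * ly, grp))
  ok <- n >= 3
  vx <- Sxx - Sx^2 / n
  slope <- ifelse(ok & vx > 0, (Sxy - Sx * Sy / n) / vx, NA_real_)
  # constant (e.g. sup-frozen) lines must fit h = 0 exactly, not a float
  # residue of the grouped sums, or threshold gates at 0 misclassify them
  slope[!is.na(slope) & abs(slope) < 1e-9] <- 0
  inter <- (Sy - slope * Sx) / n
  rss <- pmax(0, Syy - inter * Sy - slope * Sxy)
  at <- match(lines, present)
  out$h <- slope[at]
  out$logK <- inter[at]
  out$nFit <- ifelse(is.na(at), 0L, as.integer(n[at]))
  out$residual <- ifelse(!is.na(at) & ok[at], sqrt(rss[at] / n[at]), NA_real_)
  out
}

#' Ensemble mean Hoelder exponent of a skeleton subset
#'
#' The slope of the mean log2 raw modulus over the lines alive at each
#' scale, against log2 of the scale. This population-level estimate of the
#' mean line regularity is immune to the per-line selection decay that
#' biases averages of individual line fits (a line is born at an
#' extreme-value excess that fades, and dies through an annihilation
#' decay), because the living population is re-averaged at every scale.
#'
#' @param skeleton a [WtmmSkeleton-class].
#' @param lines optional integer vector restricting the subset.
#' @param fitRange numeric(2) in pixels; the default starts where the
#'   census of lines is complete (the peak of the line count, above the
#'   minimum-span censoring) and ends at the last scale with at least 5
#'   lines.
#' @return the fitted slope (dimensionless Hoelder estimate).
#' @export
skeletonMeanHoelder <- function(skeleton, lines = NULL, fitRange = NULL) {
  s <- skeleton@samples
  if (!is.null(lines)) s <- s[s$line %in% lines, , drop = FALSE]
  s <- s[s$modulus > 0, , drop = FALSE]
  if (nrow(s) == 0) stop("empty skeleton subset")
  idx <- sort(unique(s$scaleIdx))
  mlm <- tapply(log2(s$modulus), s$scaleIdx, mean)[as.character(idx)]
  n <- tapply(s$modulus, s$scaleIdx, length)[as.character(idx)]
  a <- skeleton@scales[idx]
  if (is.null(fitRange)) {
    lo <- a[max(which(n == max(n)))]
    hiOk <- which(n >= 5)
    hi <- a[if (length(hiOk)) max(hiOk) else length(a)]
    if (sum(a >= lo & a <= hi) < 3) { lo <- min(a); hi <- max(a) }
    fitRange <- c(lo, hi)
  }
  sel <- a >= fitRange[1] & a <= fitRange[2]
  if (sum(sel) < 3) stop("need at least 3 scales in the fit range")
  unname(slopeFit(mlm[sel], log(a[sel]))["slope"] * log(2) / log(2))
}

#' Export per-line features to CSV
#'
#' @param fits data.frame from [fitLineScaling()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeLineFits <- function(fits, path) {
  out <- data.frame(line_id = fits$line, anchor_x = fits$anchorX,
                    anchor_y = fits$anchorY, h = fits$h, logK = fits$logK,
                    n_scales = fits$nScales, residual = fits$residual)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
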