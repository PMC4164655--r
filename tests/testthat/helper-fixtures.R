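# Shared fixtures, computed once per test session and memoized.
# Everything is generated in code from fixed seeds; no data files.

.fixtures <- new.env(parent = emptyenv())

withFixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# Gaussian blob image, analytic form
blobImage <- function(n = 128, sx = 4, sy = 4, cx = (n - 1) / 2,
                      cy = (n - 1) / 2) {
  x <- matrix(0:(n - 1), n, n, byrow = TRUE)
  y <- matrix(0:(n - 1), n, n)
  GrayImage(exp(-((x - cx)^2 / (2 * sx^2)) - ((y - cy)^2 / (2 * sy^2))))
}

rampImage <- function(n = 128) GrayImage(matrix(0:(n - 1), n, n, byrow = TRUE))

stepImage <- function(n = 128)
  GrayImage(cbind(matrix(0, n, n / 2), matrix(1, n, n / 2)))

# full-skeleton analysis of a 512^2 fractional Brownian surface
fbmAnalysis <- function(H) {
  withFixture(paste0("fbm", round(100 * H)), {
    img <- generateFbmSurface(H, size = 512, seed = 101)
    sg <- defaultScaleGrid(img, nScales = 28, aMax = 128)
    sk <- computeSkeleton(computeScaleSpace(img, sg), minLineScales = 3)
    pf <- suppressWarnings(computePartitionFunctions(sk))
    list(img = img, sk = sk, pf = pf,
         seAuto = fitScalingExponents(pf),
         seCensus = fitScalingExponents(pf, fitRange = "census"),
         meanH = skeletonMeanHoelder(sk))
  })
}

# 20 bright spots embedded in a fatty-tissue (H = 1/3) background
spotsFixture <- function() {
  withFixture("spots", {
    bg <- generateFbmSurface(1 / 3, size = 256, seed = 21)
    set.seed(22)
    pos <- data.frame(x = runif(20, 40, 215), y = runif(20, 40, 215))
    img <- embedSpots(bg, pos, amplitude = 5 * sd(bg@.Data), radius = 1.5)
    sg <- defaultScaleGrid(img, nScales = 40, aMin = 1.5)
    ss <- computeScaleSpace(img, sg)
    sk <- computeSkeleton(ss)
    fits <- fitLineScaling(sk, fitRange = c(1.5, 10), regularized = TRUE)
    cl <- fits[is.finite(fits$h) & fits$reachesFinest, ]
    isSpot <- sapply(seq_len(nrow(cl)), function(j)
      min(sqrt((cl$anchorX[j] - pos$x)^2 + (cl$anchorY[j] - pos$y)^2))) <= 4
    list(bg = bg, pos = pos, img = img, ss = ss, sk = sk, fits = fits,
         classifiable = cl, isSpot = isSpot)
  })
}

# single-view point-model fixture: rasterized spots on a faint background,
# analysed end to end; the spectrum subset is selected by brightness
manifoldAnalysis <- function(kind, n, seed, size) {
  withFixture(paste0("man", kind, n, seed, size), {
    pts <- generateManifoldPoints(kind, n, jitter = 0.002, seed = seed)
    B <- attr(pts, "basis")
    pr <- projectAndRasterize(pts, view = B[, 3], size = size,
                              amplitude = 1, radius = 1.5)
    img <- GrayImage(pr$image@.Data +
                     0.01 * generateFbmSurface(1 / 3, size, seed + 1)@.Data)
    sg <- defaultScaleGrid(img, nScales = 40, aMin = 1.5)
    res <- runRoiAnalysis(img, gate = detectionGate(hMax = NA, logKMin = -4),
                          scaleGrid = sg)
    list(pts = pts, basis = B, positions = pr$positions, img = img,
         box = boxCountingDimension(pr$positions), res = res)
  })
}

# second (rotated) view of the same point model, for two-view case tests
manifoldSecondView <- function(kind, n, seed, size, angle = pi / 4) {
  withFixture(paste0("man2", kind, n, seed, size), {
    fix <- manifoldAnalysis(kind, n, seed, size)
    B <- fix$basis
    v2 <- cos(angle) * B[, 3] + sin(angle) * B[, 2]
    pr <- projectAndRasterize(fix$pts, view = v2, size = size,
                              amplitude = 1, radius = 1.5)
    GrayImage(pr$image@.Data +
              0.01 * generateFbmSurface(1 / 3, size, seed + 2)@.Data)
  })
}

# brute-force oracle: point in polygon over the square and four triangles,
# boundary inclusive (sum of sub-triangle areas equals the triangle area)
oracleInZone <- function(x, y, lo = 1.2, hi = 1.8) {
  inTri <- function(px, py, ax, ay, bx, by, cx, cy) {
    area <- function(x1, y1, x2, y2, x3, y3)
      abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
    A <- area(ax, ay, bx, by, cx, cy)
    s <- area(px, py, bx, by, cx, cy) + area(ax, ay, px, py, cx, cy) +
         area(ax, ay, bx, by, px, py)
    abs(s - A) <= 1e-12
  }
  ctr <- (lo + hi) / 2
  (x >= lo & x <= hi & y >= lo & y <= hi) |
    inTri(x, y, lo, lo, hi, lo, ctr, 1) |      # bottom
    inTri(x, y, lo, hi, hi, hi, ctr, 2) |      # top
    inTri(x, y, lo, lo, lo, hi, 1, ctr) |      # left
    inTri(x, y, hi, lo, hi, hi, 2, ctr)        # right
}

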