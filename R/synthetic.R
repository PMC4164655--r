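# Seeded generators for the study conditions: fractional Brownian tissue
# backgrounds, bright compact spots, diffusion-limited aggregates, 3D point
# models with projections, and the box-counting dimension oracle.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a fractional Brownian surface
#'
#' Spectral synthesis: Gaussian white noise shaped by the isotropic power
#' spectrum `(kx^2 + ky^2)^-(H + 1)`, inverse-transformed and rescaled to
#' `[0, 1]`. The field is synthesized on an `oversample`-times larger
#' periodic box and the central `size x size` window is kept, so the kept
#' window is non-periodic and carries spectral power below its own
#' fundamental (a plain one-box synthesis visibly depletes gradients at
#' scales approaching the box size). Approximately monofractal with uniform
#' Hoelder exponent `H`; `H` near 1/3 emulates fatty and near 2/3 dense
#' breast tissue texture.
#'
#' @param H Hurst exponent, strictly inside (0, 1).
#' @param size image side in pixels (>= 64).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param oversample synthesis box enlargement factor (default 2).
#' @return a [GrayImage-class] of `size x size` pixels.
#' @examples
#' img <- generateFbmSurface(0.5, size = 64, seed = 7)
#' @export
generateFbmSurface <- function(H, size = 512, seed = 1L, oversample = 2) {
  if (H <= 0 || H >= 1) stop("H must lie strictly inside (0, 1)")
  if (size < 64) stop("size must be at least 64")
  n <- as.integer(oversample * size)
  withSeed(seed, {
    noise <- matrix(rnorm(n * n), n, n)
    Fn <- fft(noise)
    k <- 2 * pi * c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
    K2 <- outer(k^2, k^2, "+")
    amp <- K2^(-(H + 1) / 2)
    amp[1, 1] <- 0                       # zero mean, no DC component
    f <- Re(fft(Fn * amp, inverse = TRUE)) / (n * n)
    i0 <- (n - size) %/% 2
    f <- f[i0 + seq_len(size), i0 + seq_len(size)]
    f <- f - min(f)
    GrayImage(f / max(f))
  })
}

#' Generate an on-lattice diffusion-limited aggregate
#'
#' Seed particle at the origin; walkers are launched on a circle (sphere in
#' 3D) of radius `R_cluster + 5`, random-walk on the lattice (with long
#' radial jumps while far from the cluster), stick on first lattice-neighbor
#' contact and are abandoned past 3x the launch radius. The result is a
#' connected cluster of exactly `n` particles; 2D aggregates have
#' box-counting dimension near the classical 1.71.
#'
#' @param n number of particles (>= 10).
#' @param dim embedding dimension, 2 or 3.
#' @param seed integer seed.
#' @return integer matrix `n x dim` of lattice coordinates.
#' @export
generateDlaCluster <- function(n, dim = 2, seed = 1L) {
  if (n < 10) stop("n must be at least 10")
  if (!dim %in% c(2, 3)) stop("embedding dimension must be 2 or 3")
  withSeed(seed, if (dim == 2) .dla2d(as.integer(n)) else .dla3d(as.integer(n)))
}

# random orthonormal basis of R^3 (uniform via QR of a Gaussian matrix)
randomBasis3 <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

#' Generate 3D point models: line, sheet or fractal cluster
#'
#' LINE: points uniform along a random 3D segment of unit length; SHEET:
#' uniform on a random planar unit-square patch; CLUSTER: a 2D
#' diffusion-limited aggregate embedded in a random 3D plane, rescaled to
#' unit diameter. Isotropic Gaussian jitter of the given amplitude is added
#' to every point.
#'
#' @param kind "LINE", "SHEET" or "CLUSTER".
#' @param n number of points (>= 10).
#' @param jitter Gaussian jitter standard deviation (same length unit as
#'   the unit-sized model; default 0).
#' @param seed integer seed.
#' @return numeric matrix `n x 3`, with attribute `basis`: the random
#'   orthonormal frame used (column 1 spans the LINE; columns 1-2 span the
#'   SHEET or CLUSTER plane, column 3 is its normal — project along it for
#'   a face-on view, along column 1 or 2 for edge-on).
#' @export
generateManifoldPoints <- function(kind = c("LINE", "SHEET", "CLUSTER"),
                                   n, jitter = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (n < 10) stop("n must be at least 10")
  if (jitter < 0) stop("jitter must be nonnegative")
  withSeed(seed, {
    B <- randomBasis3()
    pts <- switch(kind,
      LINE = {
        t <- runif(n, -0.5, 0.5)
        cbind(t, 0, 0) %*% t(B)
      },
      SHEET = {
        u <- runif(n, -0.5, 0.5); v <- runif(n, -0.5, 0.5)
        cbind(u, v, 0) %*% t(B)
      },
      CLUSTER = {
        xy <- .dla2d(as.integer(n))
        xy <- xy / max(1, 2 * max(abs(xy)))     # unit diameter
        cbind(xy[, 1], xy[, 2], 0) %*% t(B)
      })
    if (jitter > 0) pts <- pts + matrix(rnorm(3 * n, sd = jitter), n, 3)
    pts <- unname(pts)
    attr(pts, "basis") <- B
    pts
  })
}

# add Gaussian spots at subpixel 0-based positions to a matrix (in place)
splatSpots <- function(m, x, y, amplitude, radius) {
  nr <- nrow(m); nc <- ncol(m)
  w <- ceiling(3 * radius)
  for (i in seq_along(x)) {
    cx <- x[i]; cy <- y[i]
    jj <- max(0, floor(cx) - w):min(nc - 1, ceiling(cx) + w)
    ii <- max(0, floor(cy) - w):min(nr - 1, ceiling(cy) + w)
    if (!length(ii) || !length(jj)) next
    d2 <- outer((ii - cy)^2, (jj - cx)^2, "+")
    m[ii + 1, jj + 1] <- m[ii + 1, jj + 1] +
      amplitude * exp(-d2 / (2 * radius^2))
  }
  m
}

#' Orthographically project and rasterize a 3D point set
#'
#' Projects the points onto the plane orthogonal to the viewing direction,
#' maps them into the image frame with a single isotropic scale factor (so
#' relative geometry — and hence fractal dimension — is preserved), and
#' splats each as a compact Gaussian spot onto the background.
#'
#' @param points numeric matrix `n x 3`.
#' @param view unit 3-vector viewing direction (norm within 1e-9 of 1 after
#'   normalization check); default `c(0, 0, 1)`.
#' @param size image side in pixels when no background is given.
#' @param background optional [GrayImage-class] to splat onto (its
#'   dimensions override `size`).
#' @param amplitude,radius spot amplitude and Gaussian radius in pixels
#'   (defaults 1 and 1.5).
#' @param marginFrac fraction of the image side kept free on each border.
#' @return list with `image` (a [GrayImage-class]) and `positions`
#'   (data.frame `x`, `y`: 0-based projected pixel coordinates).
#' @export
projectAndRasterize <- function(points, view = c(0, 0, 1), size = 256,
                                background = NULL, amplitude = 1,
                                radius = 1.5, marginFrac = 0.1) {
  if (!is.matrix(points) || ncol(points) != 3 || nrow(points) == 0)
    stop("points must be a nonempty n x 3 matrix")
  nv <- sqrt(sum(view^2))
  if (nv < 1e-9) stop("degenerate view vector")
  v <- view / nv
  # orthonormal in-plane basis
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * v) * v; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  uv <- cbind(points %*% e1, points %*% e2)

  m <- if (is.null(background)) matrix(0, size, size)
       else background@.Data
  nr <- nrow(m); nc <- ncol(m)
  margin <- marginFrac * min(nr, nc)
  ext <- max(apply(uv, 2, function(z) diff(range(z))), .Machine$double.eps)
  sc <- (min(nr, nc) - 1 - 2 * margin) / ext
  px <- margin + (uv[, 1] - min(uv[, 1])) * sc
  py <- margin + (uv[, 2] - min(uv[, 2])) * sc
  m <- splatSpots(m, px, py, amplitude, radius)
  list(image = GrayImage(m),
       positions = data.frame(x = px, y = py))
}

#' Embed bright compact spots into a background image
#'
#' Adds Gaussian spots (default radius 1.5 px) at the given 0-based
#' positions. Positions must lie inside the image.
#'
#' @param background a [GrayImage-class].
#' @param positions data.frame with 0-based columns `x`, `y`.
#' @param amplitude peak intensity added at each spot center.
#' @param radius Gaussian radius in pixels.
#' @return a [GrayImage-class] with the spots added.
#' @export
embedSpots <- function(background, positions, amplitude, radius = 1.5) {
  m <- background@.Data
  if (any(positions$x < 0 | positions$x > ncol(m) - 1 |
          positions$y < 0 | positions$y > nrow(m) - 1))
    stop("spot positions outside the image")
  if (amplitude == 0) return(background)
  GrayImage(splatSpots(m, positions$x, positions$y, amplitude, radius),
            bitDepth = background@bitDepth)
}

#' Box-counting dimension of a 2D point set
#'
#' Counts occupied boxes over dyadic box sizes spanning the bounding square
#' and fits the slope of `log N(eps)` against `log(1 / eps)` by least
#' squares over the central range: the coarsest level is dropped and levels
#' past saturation (where most points sit alone in their box) are excluded.
#'
#' @param points numeric matrix or data.frame with two columns (x, y).
#' @param maxLevels cap on the number of dyadic levels (default 14).
#' @return list with `dimension`, `residual` (rms of the fit) and `table`
#'   (level, eps, boxes).
#' @export
boxCountingDimension <- function(points, maxLevels = 14) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  p <- unique(p)
  if (nrow(p) < 10) {
    if (nrow(unique(p)) <= 1) {
      warning("all points identical; dimension 0")
      return(list(dimension = 0, residual = 0, table = NULL))
    }
    stop("need at least 10 distinct points")
  }
  side <- max(apply(p, 2, function(z) diff(range(z))))
  if (side == 0) {
    warning("all points identical; dimension 0")
    return(list(dimension = 0, residual = 0, table = NULL))
  }
  u <- sweep(p, 2, apply(p, 2, min)) / side    # into [0, 1]^2
  nd <- nrow(u)
  lev <- 0:maxLevels
  boxes <- vapply(lev, function(k) {
    nb <- 2^k
    ix <- pmin(floor(u[, 1] * nb), nb - 1)
    iy <- pmin(floor(u[, 2] * nb), nb - 1)
    length(unique(ix * nb + iy))
  }, numeric(1))
  # fit between the coarsest level (dropped) and saturation
  kSat <- lev[which(boxes > nd / 3)[1]]
  hiK <- if (is.na(kSat)) maxLevels else max(kSat - 1, 3)
  sel <- which(lev >= 1 & lev <= hiK)
  if (length(sel) < 3) sel <- seq_along(lev)[-1]
  x <- lev[sel] * log(2)                       # log(1/eps)
  y <- log(boxes[sel])
  ft <- slopeFit(y, x)
  res <- y - mean(y) - ft["slope"] * (x - mean(x))
  list(dimension = unname(ft["slope"]),
       residual = sqrt(mean(res^2)),
       table = data.frame(level = lev, eps = side / 2^lev, boxes = boxes))
}
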