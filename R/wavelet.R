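# Gradient-of-Gaussian scale space, computed spectrally.
#
# Convention: T(b, a) = a * grad(phi_a * f)(b) with an L1-normalized Gaussian
# phi_a of standard deviation a pixels. Under this normalization a step edge
# has scale-independent modulus (h = 0) and an H-Hoelder texture scales as
# a^H, which is the reference frame for the per-line power-law fits.

# next FFT-friendly length (2^a * 3^b * 5^c)
nextNice <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(n)
    n <- n + 1
  }
}

# reflect 0-based index k into 0..(n-1), symmetric with edge repeat
reflectIndex <- function(k, n) {
  r <- k %% (2L * n)
  r <- ifelse(r < 0, r + 2L * n, r)
  ifelse(r >= n, 2L * n - 1L - r, r)
}

#' Default logarithmic scale grid for an image
#'
#' 40 logarithmically spaced scales from `aMin = 3` pixels to
#' `min(width, height) / 4`, covering the range over which lesion-scale
#' power-law behavior is fitted on regions of 256^2 pixels and above.
#'
#' @param image a [GrayImage-class] or a matrix.
#' @param nScales number of scales (default 40).
#' @param aMin,aMax scale bounds in pixels; `aMax` defaults to
#'   `min(width, height) / 4` and may not exceed it.
#' @return numeric vector of scales, strictly increasing.
#' @export
defaultScaleGrid <- function(image, nScales = 40, aMin = 3, aMax = NULL) {
  lim <- min(dim(image)) / 4
  if (is.null(aMax)) aMax <- lim
  if (aMax > lim)
    stop(sprintf("aMax = %g exceeds min(width, height)/4 = %g", aMax, lim))
  if (aMin < 1) stop("aMin must be at least 1 pixel")
  if (aMin >= aMax) stop("aMin must be below aMax")
  exp(seq(log(aMin), log(aMax), length.out = nScales))
}

#' Compute the gradient-of-Gaussian scale space of an image
#'
#' For each scale `a` the image is convolved with an L1-normalized Gaussian
#' of standard deviation `a` pixels and the gradient is taken spectrally
#' (exact derivative of the Gaussian kernel), scaled by `a`. The modulus is
#' the Euclidean norm of the two components and the argument their angle.
#' Convolution uses the FFT with mirror (reflect) padding; the padded region
#' is cropped before output. The per-scale border margin `ceiling(3a)` marks
#' pixels whose response leaks across the image boundary.
#'
#' @param image a [GrayImage-class] or numeric matrix with finite values,
#'   at least 64 x 64.
#' @param scaleGrid numeric vector of scales (pixels), strictly increasing;
#'   defaults to [defaultScaleGrid()].
#' @return a [ScaleSpace-class].
#' @examples
#' ramp <- GrayImage(matrix(rep(0:63, each = 64), 64, 64, byrow = TRUE))
#' ss <- computeScaleSpace(ramp, defaultScaleGrid(ramp, nScales = 5))
#' # interior modulus equals the scale for a unit ramp
#' modulus(ss, 1)[32, 32]
#' @export
computeScaleSpace <- function(image, scaleGrid = defaultScaleGrid(image)) {
  m <- if (is(image, "GrayImage")) image@.Data else as.matrix(image)
  if (any(!is.finite(m))) stop("image contains non-finite pixels")
  if (nrow(m) < 64 || ncol(m) < 64) stop("image must be at least 64 x 64")
  if (length(scaleGrid) == 0) stop("scale grid is empty")
  if (any(diff(scaleGrid) <= 0)) stop("scales must be strictly increasing")
  if (max(scaleGrid) > min(dim(m)) / 4)
    stop("largest scale exceeds min(width, height)/4 for this image")

  nr <- nrow(m); nc <- ncol(m)
  pad <- ceiling(3 * max(scaleGrid))
  Nr <- nextNice(nr + 2L * pad)
  Nc <- nextNice(nc + 2L * pad)
  # mirror-pad: place the image at offset `pad`, fill the rest by reflection
  ridx <- reflectIndex(seq_len(Nr) - 1L - pad, nr) + 1L
  cidx <- reflectIndex(seq_len(Nc) - 1L - pad, nc) + 1L
  padded <- m[ridx, cidx, drop = FALSE]

  F <- fft(padded)
  # angular frequencies of the DFT grid
  kr <- 2 * pi * c(0:floor(Nr / 2), -(ceiling(Nr / 2) - 1):-1)[1:Nr] / Nr
  kc <- 2 * pi * c(0:floor(Nc / 2), -(ceiling(Nc / 2) - 1):-1)[1:Nc] / Nc
  KY <- matrix(kr, Nr, Nc)              # row frequency = y (downward)
  KX <- matrix(kc, Nr, Nc, byrow = TRUE)
  K2 <- KX^2 + KY^2

  rows <- pad + seq_len(nr); cols <- pad + seq_len(nc)
  n <- length(scaleGrid)
  mod <- vector("list", n); arg <- vector("list", n)
  for (i in seq_len(n)) {
    a <- scaleGrid[i]
    GF <- exp(-(a^2 / 2) * K2) * F
    T1 <- Re(fft((1i * a) * KX * GF, inverse = TRUE)) / (Nr * Nc)
    T2 <- Re(fft((1i * a) * KY * GF, inverse = TRUE)) / (Nr * Nc)
    T1 <- T1[rows, cols]; T2 <- T2[rows, cols]
    mod[[i]] <- sqrt(T1^2 + T2^2)
    arg[[i]] <- atan2(T2, T1)
  }
  new("ScaleSpace", scales = as.numeric(scaleGrid), modulus = mod,
      argument = arg, borderMargin = as.integer(ceiling(3 * scaleGrid)),
      imageDim = c(nr, nc), imageMax = max(abs(m)))
}
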