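test_that("fractional Brownian surfaces have the prescribed roughness", {
  img <- generateFbmSurface(0.5, size = 512, seed = 3)@.Data
  lags <- c(2, 4, 8, 16, 32)
  s2 <- sapply(lags, function(d) {
    dx <- img[, (1 + d):512] - img[, 1:(512 - d)]
    dy <- img[(1 + d):512, ] - img[1:(512 - d), ]
    mean(c(dx^2, dy^2))
  })
  hEst <- coef(lm(log(s2) ~ log(lags)))[2] / 2
  expect_equal(unname(hEst), 0.5, tolerance = 0.1)

  # deterministic given the seed
  expect_identical(generateFbmSurface(1 / 3, 128, seed = 9)@.Data,
                   generateFbmSurface(1 / 3, 128, seed = 9)@.Data)
  expect_false(identical(generateFbmSurface(1 / 3, 128, seed = 9)@.Data,
                         generateFbmSurface(1 / 3, 128, seed = 10)@.Data))

  # smoother surfaces have less total variation
  tv <- function(m) mean(abs(diff(m)))
  expect_lt(tv(generateFbmSurface(0.99, 128, seed = 2)@.Data),
            tv(generateFbmSurface(0.01, 128, seed = 2)@.Data))

  expect_error(generateFbmSurface(1.5, 128), "inside")
  expect_error(generateFbmSurface(0.5, 32), "at least 64")
})

test_that("diffusion-limited aggregates are connected with the known dimension", {
  d <- generateDlaCluster(2000, 2, seed = 5)
  expect_equal(nrow(unique(d)), 2000)
  # every particle touches the cluster grown before it
  occ <- new.env(hash = TRUE)
  occ[[paste(d[1, ], collapse = ",")]] <- TRUE
  for (i in 2:nrow(d)) {
    nb <- any(vapply(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)),
                     function(o) isTRUE(occ[[paste(d[i, ] + o,
                                                   collapse = ",")]]),
                     logical(1)))
    expect_true(nb)
    occ[[paste(d[i, ], collapse = ",")]] <- TRUE
  }

  d4 <- generateDlaCluster(10000, 2, seed = 5)
  expect_equal(boxCountingDimension(d4)$dimension, 1.71, tolerance = 0.15)

  # a 3D aggregate projects to a much denser, near-plane-filling set
  d3 <- generateDlaCluster(20000, 3, seed = 7)
  proj <- boxCountingDimension(d3[, 1:2])$dimension
  expect_gt(proj, boxCountingDimension(d4)$dimension)
  expect_gt(proj, 1.7)

  expect_error(generateDlaCluster(5), "at least 10")
  expect_error(generateDlaCluster(100, dim = 4), "2 or 3")
})

test_that("manifold point models are exact at zero jitter", {
  ln <- generateManifoldPoints("LINE", 50, jitter = 0, seed = 1)
  # collinear: rank-1 after centering
  expect_lt(svd(scale(ln, scale = FALSE))$d[2], 1e-10)

  sh <- generateManifoldPoints("SHEET", 50, jitter = 0, seed = 1)
  expect_lt(svd(scale(sh, scale = FALSE))$d[3], 1e-10)
  expect_gt(svd(scale(sh, scale = FALSE))$d[2], 1e-3)

  cl <- generateManifoldPoints("CLUSTER", 10000, jitter = 0, seed = 8)
  B <- attr(cl, "basis")
  uv <- cbind(cl %*% B[, 1], cl %*% B[, 2])
  expect_equal(boxCountingDimension(uv)$dimension, 1.71, tolerance = 0.15)

  expect_error(generateManifoldPoints("BLOB", 50), "arg")
})

test_that("projection views control the apparent dimension", {
  ln <- generateManifoldPoints("LINE", 2000, jitter = 0, seed = 2)
  B <- attr(ln, "basis")
  # viewing perpendicular to the segment keeps it one-dimensional
  pr <- projectAndRasterize(ln, view = B[, 3], size = 256)
  expect_equal(boxCountingDimension(pr$positions)$dimension, 1,
               tolerance = 0.1)

  sh <- generateManifoldPoints("SHEET", 20000, jitter = 0, seed = 2)
  Bs <- attr(sh, "basis")
  faceOn <- projectAndRasterize(sh, view = Bs[, 3], size = 256)
  edgeOn <- projectAndRasterize(sh, view = Bs[, 1], size = 256)
  # the rotated patch's bounding box inflates coarse-level box counts,
  # biasing the estimate a little below the true dimension 2
  expect_equal(boxCountingDimension(faceOn$positions)$dimension, 2,
               tolerance = 0.2)
  expect_equal(boxCountingDimension(edgeOn$positions)$dimension, 1,
               tolerance = 0.15)

  # translating the points translates nothing: the frame is normalized
  pr2 <- projectAndRasterize(ln + 5, view = B[, 3], size = 256)
  expect_equal(pr$image@.Data, pr2$image@.Data, tolerance = 1e-9)

  expect_error(projectAndRasterize(ln, view = c(0, 0, 0)), "degenerate")
})

test_that("spot embedding is exact and bounded", {
  bg <- GrayImage(matrix(0.2, 128, 128))
  expect_identical(embedSpots(bg, data.frame(x = 10, y = 10), 0)@.Data,
                   bg@.Data)
  one <- embedSpots(bg, data.frame(x = 63.5, y = 40), amplitude = 1,
                    radius = 1.5)
  peak <- which(one@.Data == max(one@.Data), arr.ind = TRUE)
  expect_true(all(abs(peak[, "col"] - 1 - 63.5) <= 0.5))
  expect_true(all(abs(peak[, "row"] - 1 - 40) <= 0.5))
  expect_error(embedSpots(bg, data.frame(x = 200, y = 10), 1), "outside")
})

test_that("box counting recovers known dimensions", {
  expect_warning(r0 <- boxCountingDimension(matrix(1, 20, 2)), "identical")
  expect_equal(r0$dimension, 0)

  g <- as.matrix(expand.grid(0:255, 0:255))
  expect_equal(boxCountingDimension(g)$dimension, 2, tolerance = 0.05)

  set.seed(11)
  t <- runif(1e4)
  expect_equal(boxCountingDimension(cbind(t, 0.3 * t))$dimension, 1,
               tolerance = 0.05)

  expect_error(boxCountingDimension(cbind(1:5, 1:5)), "at least 10")
})
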