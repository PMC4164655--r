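test_that("maxima chains match closed-form fixtures", {
  sg <- defaultScaleGrid(matrix(0, 128, 128), nScales = 6)

  # constant modulus everywhere: no directional maximum exists
  ramp <- computeScaleSpace(rampImage(128), sg)
  for (i in 1:4)
    expect_equal(nrow(extractMaximaChains(ramp, i)), 0)

  # half-plane step edge: one chain tracing the edge line
  step <- computeScaleSpace(stepImage(128), sg)
  ch <- extractMaximaChains(step, 2)
  expect_equal(length(unique(ch$chain)), 1)
  expect_true(all(ch$x %in% c(63, 64)))

  # isotropic blob: one closed ring whose radius grows with scale
  blob <- computeScaleSpace(blobImage(128, 4, 4), sg)
  r <- sapply(c(1, 3), function(i) {
    ch <- extractMaximaChains(blob, i)
    expect_equal(length(unique(ch$chain)), 1)
    mean(sqrt((ch$x - 63.5)^2 + (ch$y - 63.5)^2))
  })
  # ring radius ~ sqrt(a^2 + sigma^2)
  expect_equal(r[1], sqrt(sg[1]^2 + 16), tolerance = 0.15)
  expect_lt(r[1], r[2])

  # ordered output: consecutive points of the ring are 8-adjacent
  # (locally thick knots of the discrete ring may force a rare re-entry)
  chO <- extractMaximaChains(blob, 1, ordered = TRUE)
  d <- sqrt(diff(chO$x)^2 + diff(chO$y)^2)
  expect_true(all(d <= sqrt(2) + 1e-9))
  # at coarser scales the discrete ring carries a few 2-px-thick knots
  # where no strict path exists; ordering must still be overwhelmingly
  # contiguous (an unordered return would score near 0.1 here)
  chO2 <- extractMaximaChains(blob, 2, ordered = TRUE)
  d2 <- sqrt(diff(chO2$x)^2 + diff(chO2$y)^2)
  expect_gte(mean(d2 <= sqrt(2) + 1e-9), 0.85)

  expect_error(extractMaximaChains(blob, 99), "outside the grid")
})

test_that("WTMMM are the modulus maxima along chains, with tie collapse", {
  # hand-built open chain with a single interior peak
  chain <- data.frame(chain = 1L, x = 0:6, y = rep(3, 7),
                      modulus = c(1, 2, 3, 5, 3, 2, 1),
                      argument = 0)
  attr(chain, "imageDim") <- c(10L, 10L)
  w <- locateWtmmm(chain)
  expect_equal(nrow(w), 1)
  expect_equal(w$x, 3)

  # closed chain with constant modulus: exactly one representative,
  # the smallest (y, x) position
  th <- seq(0, 2 * pi, length.out = 200)[-200]
  ring <- data.frame(chain = 1L,
                     x = round(8 + 5 * cos(th)), y = round(8 + 5 * sin(th)),
                     modulus = 2, argument = 0)
  ring <- ring[!duplicated(ring[c("x", "y")]), ]
  attr(ring, "imageDim") <- c(20L, 20L)
  wr <- locateWtmmm(ring)
  expect_equal(nrow(wr), 1)
  ord <- order(ring$y, ring$x)
  expect_equal(c(wr$x, wr$y), c(ring$x[ord[1]], ring$y[ord[1]]))

  # anisotropic blob: maxima concentrate at the two ends of the
  # steepest-gradient axis
  sg <- defaultScaleGrid(matrix(0, 128, 128), nScales = 6)
  ell <- computeScaleSpace(blobImage(128, 6, 3), sg)
  we <- locateWtmmm(extractMaximaChains(ell, 2))
  expect_true(nrow(we) %in% c(2, 4))
  expect_true(all(abs(we$x - 63.5) < 2))   # on the vertical (steep) axis

  expect_equal(nrow(locateWtmmm(ring[0, ])), 0)
})

test_that("skeleton lines anchor on isolated bright spots", {
  bg <- GrayImage(matrix(0.5, 128, 128))
  sg <- defaultScaleGrid(bg, nScales = 16)

  one <- embedSpots(bg, data.frame(x = 63, y = 63), amplitude = 1,
                    radius = 1.5)
  sk1 <- computeSkeleton(computeScaleSpace(one, sg), minLineScales = 8)
  a1 <- anchors(sk1)
  expect_gte(nrow(a1), 1)
  # anchors sit on the smallest-scale maxima ring, radius sqrt(a^2 + r^2)
  expect_lte(min(sqrt((a1$x - 63)^2 + (a1$y - 63)^2)), 4)

  two <- embedSpots(bg, data.frame(x = c(33, 93), y = c(63, 63)),
                    amplitude = 1, radius = 1.5)
  sk2 <- computeSkeleton(computeScaleSpace(two, sg), minLineScales = 8)
  a2 <- anchors(sk2)
  d1 <- sqrt((a2$x - 33)^2 + (a2$y - 63)^2)
  d2 <- sqrt((a2$x - 93)^2 + (a2$y - 63)^2)
  expect_gte(sum(d1 <= 5), 1)
  expect_gte(sum(d2 <= 5), 1)
  # no anchor in the no-man's land between the two spots
  expect_true(all(pmin(d1, d2) <= 15))
  # no line jumps between the spots at fine scales
  s <- skeletonSamples(sk2)
  fine <- s[s$scaleIdx <= 8, ]
  side <- tapply(fine$x < 63, fine$line, function(z) length(unique(z)))
  expect_true(all(side == 1))

  # empty input, and a grid shorter than the minimum span
  emptyW <- lapply(1:16, function(i)
    data.frame(chain = integer(), x = numeric(), y = numeric(),
               modulus = numeric()))
  expect_equal(nLines(buildSkeleton(emptyW, sg, imageDim = c(128L, 128L))), 0)
  expect_error(buildSkeleton(emptyW[1:4], sg[1:4], minLineScales = 10),
               "shorter than")
})

test_that("skeleton samples are one per scale and strictly increasing", {
  fix <- spotsFixture()
  s <- skeletonSamples(fix$sk)
  bad <- tapply(s$scaleIdx, s$line, function(ix)
    any(duplicated(ix)) || any(diff(sort(ix)) != 1))
  expect_false(any(bad))
})

test_that("per-line power-law fits are exact on synthetic lines", {
  # modulus = K * a^h exactly, K = 4, h = -1
  a <- 2^seq(1, 4, length.out = 12)
  samples <- data.frame(line = 1L, scaleIdx = 1:12, scale = a,
                        x = 0, y = 0, modulus = 4 * a^(-1))
  sk <- new("WtmmSkeleton", samples = samples, scales = a,
            minLineScales = 3L, imageDim = c(NA_integer_, NA_integer_))
  ft <- fitLineScaling(sk)
  expect_equal(ft$h, -1, tolerance = 1e-12)
  expect_equal(ft$logK, 2, tolerance = 1e-12)
  expect_equal(ft$residual, 0, tolerance = 1e-10)

  # the regularized fit of a decaying line is exactly flat
  ftReg <- fitLineScaling(sk, regularized = TRUE)
  expect_identical(ftReg$h, 0)

  # too few samples in range: NA fit
  ft2 <- fitLineScaling(sk, fitRange = c(2, 2.5))
  expect_true(is.na(ft2$h))
})

test_that("chain count at the finest scale is stable under faint noise", {
  fix <- spotsFixture()
  base <- extractMaximaChains(fix$ss, 1, ordered = FALSE)
  set.seed(77)
  noisy <- GrayImage(fix$img@.Data +
                     rnorm(length(fix$img@.Data),
                           sd = 0.001 * diff(range(fix$img@.Data))))
  sg <- defaultScaleGrid(noisy, nScales = 40, aMin = 1.5)
  ssN <- computeScaleSpace(noisy, sg[1:2])
  pert <- extractMaximaChains(ssN, 1, ordered = FALSE)
  n0 <- length(unique(base$chain)); n1 <- length(unique(pert$chain))
  expect_lte(abs(n1 - n0) / n0, 0.05)
})
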