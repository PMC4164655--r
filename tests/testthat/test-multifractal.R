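# small synthetic skeleton: nLines lines over the given scales with
# modulus values supplied per line (constant along the line)
syntheticSkeleton <- function(mods, a = 2^seq(0, 3, length.out = 8)) {
  n <- length(mods)
  samples <- data.frame(
    line = rep(seq_len(n), each = length(a)),
    scaleIdx = rep(seq_along(a), n),
    scale = rep(a, n),
    x = rep(seq_len(n) * 10, each = length(a)), y = 0,
    modulus = rep(mods, each = length(a)))
  new("WtmmSkeleton", samples = samples, scales = a,
      minLineScales = 3L, imageDim = c(NA_integer_, NA_integer_))
}

test_that("partition functions have their closed forms on degenerate input", {
  q <- seq(-2, 4, by = 0.5)

  # a single line of constant modulus 2
  pf1 <- computePartitionFunctions(syntheticSkeleton(2), q = q)
  expect_equal(pf1@logZ, outer(q, rep(log(2), 8)), tolerance = 1e-12)
  expect_true(all(abs(pf1@hqa - log(2)) < 1e-12))
  expect_true(all(abs(pf1@dqa) < 1e-12))

  # eight identical lines: equal weights 1/8, entropy -log 8
  pf8 <- computePartitionFunctions(syntheticSkeleton(rep(3, 8)), q = q)
  expect_true(all(abs(pf8@dqa + log(8)) < 1e-12))
  expect_equal(pf8@nLines, rep(8L, 8))

  # Z(0, a) equals the number of contributing lines for any input
  pfm <- computePartitionFunctions(syntheticSkeleton(c(1, 2, 4, 8)), q = q)
  expect_equal(exp(pfm@logZ[q == 0, ]), rep(4, 8), tolerance = 1e-12)

  expect_error(computePartitionFunctions(syntheticSkeleton(2), q = c(1, 2)),
               "q = 0")
  expect_error(computePartitionFunctions(syntheticSkeleton(2),
                                         lines = 99L), "empty")
})

test_that("Boltzmann weights are normalized to 1e-10 at every (q, a)", {
  fix <- spotsFixture()
  pf <- suppressWarnings(computePartitionFunctions(fix$sk))
  s <- skeletonSamples(fix$sk)
  s <- s[order(s$line, s$scaleIdx), ]
  sup <- ave(s$modulus, s$line, FUN = cummax)
  for (j in c(1, 10, 25)) {
    lv <- log(sup[s$scaleIdx == j])
    for (qv in c(-2, -0.5, 0, 1, 4)) {
      k <- which(pf@q == qv)
      w <- exp(qv * lv - pf@logZ[k, j])
      expect_lt(abs(sum(w) - 1), 1e-10)
      expect_true(all(w >= 0 & w <= 1))
    }
  }
})

test_that("scaling exponents recover an exactly power-law partition function", {
  # Z(q, a) = a^(2q - 1) exactly
  a <- 2^seq(0, 4, length.out = 10)
  q <- seq(-2, 4, by = 0.25)
  logZ <- outer(q, log(a), function(qq, la) (2 * qq - 1) * la)
  pf <- new("PartitionFunctions", q = q, scales = a, logZ = logZ,
            hqa = outer(q, log(a), function(qq, la) 2 * la),
            dqa = outer(q, log(a), function(qq, la) -la),
            nLines = rep(100L, 10))
  se <- fitScalingExponents(pf, fitRange = range(a))
  expect_equal(se@tau, 2 * q - 1, tolerance = 1e-10)
  expect_equal(se@r2, rep(1, length(q)), tolerance = 1e-10)
  expect_false(any(se@flagged))
  expect_equal(se@hq, rep(2, length(q)), tolerance = 1e-10)
  expect_equal(se@dq, rep(-1, length(q)), tolerance = 1e-10)
})

test_that("a monofractal exponent set collapses to a point spectrum", {
  q <- seq(-2, 4, by = 0.25)
  se <- new("ScalingExponents", q = q, tau = 0.5 * q - 2,
            hq = rep(0.5, length(q)), dq = rep(2, length(q)),
            r2 = rep(1, length(q)), flagged = rep(FALSE, length(q)),
            fitRange = c(1, 16))
  sp <- singularitySpectrum(se)
  expect_equal(unique(sp@h), 0.5)
  expect_equal(unique(sp@D), 2)
  expect_equal(supportDimension(sp), 2)
  expect_equal(sp@DFmax, 2)
  expect_true(all(abs(sp@legendreGap) < 1e-12))

  seBad <- se
  seBad@flagged[q == 0] <- TRUE
  expect_error(singularitySpectrum(seBad), "flagged")
})

test_that("the support-dimension identity tau(0) = -D_F holds on textures", {
  fx <- fbmAnalysis(0.5)
  se <- fx$seCensus
  i0 <- which(se@q == 0)
  expect_lt(abs(se@tau[i0] + se@dq[i0]), 0.1)
  # full-skeleton support of a dense texture fills the plane
  expect_equal(se@dq[i0], 2, tolerance = 0.15)
})
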