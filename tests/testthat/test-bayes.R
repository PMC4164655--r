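test_that("the assessment-score prior mean mixes historical rates", {
  expect_equal(trunc(biradsPriorMean(c(1, 47, 11), 59) * 1e4) / 1e4,
               0.3885)
  expect_equal(biradsPriorMean(c(1, 47, 11), 59), 22.925 / 59,
               tolerance = 1e-12)
  # equal per-score probabilities collapse to p * coverage
  expect_equal(biradsPriorMean(c(3, 4, 5), 20, probs = rep(0.4, 3)),
               0.4 * 12 / 20)
  expect_equal(biradsPriorMean(c(0, 0, 10), 10), 0.95)
  expect_error(biradsPriorMean(c(1, 1, 1), 0), "positive")
  expect_error(biradsPriorMean(c(5, 5, 5), 10), "exceed")
})

test_that("method-of-moments Beta construction matches closed forms", {
  u <- betaFromMeanSd(0.5, sqrt(1 / 12))
  expect_equal(u@alpha, 1, tolerance = 1e-9)
  expect_equal(u@beta, 1, tolerance = 1e-9)

  b <- betaFromMeanSd(0.3885, 0.25)
  expect_equal(betaMean(b), 0.3885, tolerance = 1e-12)
  expect_equal(betaSd(b), 0.25, tolerance = 1e-12)
  expect_equal(b@alpha, 1.09, tolerance = 0.01)
  expect_equal(b@beta, 1.71, tolerance = 0.01)

  # the mirrored mean swaps the shape parameters
  m <- betaFromMeanSd(1 - 0.3885, 0.25)
  expect_equal(m@alpha, b@beta, tolerance = 1e-12)
  expect_equal(m@beta, b@alpha, tolerance = 1e-12)

  expect_error(betaFromMeanSd(0.5, 0.6), "must be below")
  expect_error(betaFromMeanSd(1.2, 0.1), "inside")
})

test_that("conjugate updating adds counts, including the printed cases", {
  p <- posteriorUpdate(betaSpec(1, 1), 3, 10)
  expect_equal(c(p@alpha, p@beta), c(4, 8))

  pm <- posteriorUpdate(betaSpec(1.09241, 1.71223), 23, 25)
  expect_equal(c(pm@alpha, pm@beta), c(24.09241, 3.71223), tolerance = 1e-12)
  pb <- posteriorUpdate(betaSpec(1.71223, 1.09241), 30, 34)
  expect_equal(c(pb@alpha, pb@beta), c(31.71223, 5.09241), tolerance = 1e-12)

  # updating with no data is the identity
  id <- posteriorUpdate(betaSpec(2.5, 3.5), 0, 0)
  expect_equal(c(id@alpha, id@beta), c(2.5, 3.5))
  expect_error(posteriorUpdate(betaSpec(1, 1), 5, 3), "successes")
})

test_that("the HDI is the narrowest interval with the requested mass", {
  # symmetric density: interval symmetric about 1/2
  h <- betaHdi(betaSpec(50, 50), 0.95)
  expect_equal(h@lower + h@upper, 1, tolerance = 1e-6)
  expect_equal(pbeta(h@upper, 50, 50) - pbeta(h@lower, 50, 50), 0.95,
               tolerance = 1e-8)

  # printed malignant-direction posterior
  hm <- betaHdi(betaSpec(24.09241, 3.71223))
  expect_equal(round(hm@lower, 3), 0.742)
  expect_equal(round(hm@upper, 3), 0.975)

  # interior solutions have equal density at both endpoints
  expect_equal(dbeta(hm@lower, 24.09241, 3.71223),
               dbeta(hm@upper, 24.09241, 3.71223), tolerance = 1e-3)

  # flat density: tie broken by centering
  hu <- betaHdi(betaSpec(1, 1), 0.9)
  expect_equal(c(hu@lower, hu@upper), c(0.05, 0.95))

  # never wider than the equal-tailed interval of the same mass
  set.seed(8)
  for (i in 1:25) {
    al <- runif(1, 0.5, 40); be <- runif(1, 0.5, 40)
    if (al <= 1 && be <= 1) next
    hd <- betaHdi(betaSpec(al, be), 0.9)
    eti <- qbeta(c(0.05, 0.95), al, be)
    expect_lte(hd@upper - hd@lower, diff(eti) + 1e-7)
  }
  expect_error(betaHdi(betaSpec(2, 2), 1.2), "inside")
})

test_that("Monte Carlo predictive tails match the exact Beta-binomial law", {
  spec <- betaSpec(24.09241, 3.71223)
  pr <- posteriorPredictiveTail(spec, 27, 23, nIter = 50000, seed = 4)
  expect_equal(sum(pr@freq), 1, tolerance = 1e-12)
  exact <- betaBinomialTail(spec, 27, 23)
  se <- sqrt(exact * (1 - exact) / 50000)
  expect_lt(abs(pr@tailProb - exact), 3 * se)

  # degenerate tail
  full <- posteriorPredictiveTail(betaSpec(2, 2), 10, 10, nIter = 1000,
                                  seed = 1)
  expect_equal(full@tailProb, 1)

  # seeded reproducibility without disturbing the session RNG
  a1 <- posteriorPredictiveTail(spec, 27, 23, nIter = 2000, seed = 7)
  a2 <- posteriorPredictiveTail(spec, 27, 23, nIter = 2000, seed = 7)
  expect_identical(a1@freq, a2@freq)
  set.seed(99); x1 <- runif(1)
  invisible(posteriorPredictiveTail(spec, 27, 23, nIter = 2000, seed = 7))
  x2 <- runif(1)
  set.seed(99)
  expect_identical(runif(2), c(x1, x2))

  expect_error(posteriorPredictiveTail(spec, 27, 23, nIter = 0), "positive")
  expect_error(posteriorPredictiveTail(spec, 27, 28), "kObs")
})
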