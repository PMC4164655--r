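#' Prior mean from a BI-RADS composition
#'
#' Mixes the historical per-score malignancy probabilities by the observed
#' prevalence of BI-RADS assessment scores 3, 4 and 5 in a case set:
#' `sum((count_i / N) * p_i)`. The default probabilities are the historical
#' rates 2% (score 3), 26.5% (score 4, midpoint of the reported 23-30%
#' interval) and 95% (score 5).
#'
#' @param counts integer(3); cases with assessment scores 3, 4, 5.
#' @param n total number of cases (must be positive; `sum(counts) <= n`).
#' @param probs per-score malignancy probabilities.
#' @return the mixture mean, a probability in `[0, 1]`.
#' @examples
#' biradsPriorMean(c(1, 47, 11), 59)  # 0.38856
#' @export
biradsPriorMean <- function(counts, n = sum(counts),
                            probs = c(0.02, 0.265, 0.95)) {
  if (length(counts) != length(probs))
    stop("need one count per probability")
  if (any(counts < 0) || any(probs < 0) || any(probs > 1))
    stop("counts must be nonnegative and probs in [0, 1]")
  if (n <= 0) stop("total case count must be positive")
  if (sum(counts) > n) stop("counts exceed the total")
  sum((counts / n) * probs)
}

#' Beta distribution from a mean and standard deviation
#'
#' Method of moments: `kappa = mean * (1 - mean) / sd^2 - 1`,
#' `alpha = mean * kappa`, `beta = (1 - mean) * kappa`. The moments are
#' attainable only when `sd^2 < mean * (1 - mean)`.
#'
#' @param mean target mean in (0, 1).
#' @param sd target standard deviation.
#' @return a [BetaSpec-class].
#' @examples
#' beta_from <- betaFromMeanSd(0.5, sqrt(1 / 12))  # Beta(1, 1)
#' @export
betaFromMeanSd <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("mean must lie strictly inside (0, 1)")
  if (sd^2 >= mean * (1 - mean))
    stop("sd^2 must be below mean * (1 - mean) for a Beta distribution")
  kappa <- mean * (1 - mean) / sd^2 - 1
  betaSpec(mean * kappa, (1 - mean) * kappa)
}

#' Conjugate Bernoulli-Beta posterior update
#'
#' @param prior a [BetaSpec-class].
#' @param successes,trials observed Bernoulli counts.
#' @return the posterior `Beta(alpha + successes, beta + trials - successes)`.
#' @examples
#' posteriorUpdate(betaSpec(1, 1), 3, 10)  # Beta(4, 8)
#' @export
posteriorUpdate <- function(prior, successes, trials) {
  if (successes < 0 || trials < 0 || successes > trials)
    stop("need 0 <= successes <= trials")
  betaSpec(prior@alpha + successes, prior@beta + trials - successes)
}

#' Highest density interval of a Beta distribution
#'
#' The narrowest interval holding the requested posterior mass, found by a
#' one-dimensional search over the lower endpoint: for each candidate lower
#' bound `lo` the matching upper bound is `qbeta(pbeta(lo) + mass)`, and the
#' width is minimized. For a unimodal density this interval is unique; the
#' flat `Beta(1, 1)` case is resolved by centering on 0.5.
#'
#' @param spec a [BetaSpec-class].
#' @param mass interval mass in (0, 1); default 0.95.
#' @return an [HdiInterval-class].
#' @examples
#' betaHdi(betaSpec(24.09241, 3.71223))  # approx [0.742, 0.975]
#' @export
betaHdi <- function(spec, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must lie strictly inside (0, 1)")
  a <- spec@alpha; b <- spec@beta
  if (a == 1 && b == 1) {
    half <- mass / 2
    return(new("HdiInterval", lower = 0.5 - half, upper = 0.5 + half,
               mass = mass))
  }
  width <- function(lo) qbeta(pbeta(lo, a, b) + mass, a, b) - lo
  hi0 <- qbeta(1 - mass, a, b)
  if (hi0 <= .Machine$double.eps) {   # mode at 0: interval starts there
    lo <- 0
  } else {
    opt <- optimize(width, c(0, hi0), tol = 1e-10)
    lo <- opt$minimum
    # the optimum can sit on the boundary for monotone densities
    if (width(0) <= opt$objective) lo <- 0
  }
  new("HdiInterval", lower = lo, upper = lo + width(lo), mass = mass)
}

#' Posterior-predictive tail probability by Monte Carlo
#'
#' Repeats `nIter` times: draw a success probability from `spec`, then a
#' count `k` from `Binomial(nTrials, theta)`; returns the normalized
#' histogram of `k` and the fraction of draws with `k <= kObs`. Reproducible
#' for a given `seed` (the R random-number generator state is saved and
#' restored).
#'
#' @param spec a [BetaSpec-class] (typically a posterior).
#' @param nTrials number of Bernoulli trials per draw.
#' @param kObs observed count whose lower tail is evaluated.
#' @param nIter number of Monte Carlo iterations (default 100000).
#' @param seed integer seed.
#' @return a [PredictiveResult-class].
#' @examples
#' posteriorPredictiveTail(betaSpec(4, 8), 10, 3, nIter = 1000, seed = 1)
#' @export
posteriorPredictiveTail <- function(spec, nTrials, kObs, nIter = 100000,
                                    seed = 1L) {
  if (nIter <= 0) stop("nIter must be positive")
  if (nTrials < 1) stop("nTrials must be at least 1")
  if (kObs < 0 || kObs > nTrials) stop("kObs must lie in 0..nTrials")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  theta <- rbeta(nIter, spec@alpha, spec@beta)
  k <- rbinom(nIter, nTrials, theta)
  counts <- tabulate(k + 1L, nbins = nTrials + 1L)
  new("PredictiveResult",
      k = 0:nTrials, freq = counts / nIter,
      tailProb = sum(counts[seq_len(kObs + 1L)]) / nIter,
      kObs = as.integer(kObs), nTrials = as.integer(nTrials),
      nIter = as.integer(nIter), seed = as.integer(seed))
}

#' Exact Beta-binomial lower-tail probability
#'
#' Closed-form counterpart of [posteriorPredictiveTail()]: when theta follows
#' `Beta(alpha, beta)` and `k | theta` is binomial, `k` is Beta-binomial and
#' `P(k <= kObs)` has an exact expression. Used as an independent check of
#' the Monte Carlo estimate.
#'
#' @param spec a [BetaSpec-class].
#' @param nTrials,kObs binomial setup as in [posteriorPredictiveTail()].
#' @return exact tail probability.
#' @export
betaBinomialTail <- function(spec, nTrials, kObs) {
  k <- 0:kObs
  sum(exp(lchoose(nTrials, k) +
          lbeta(k + spec@alpha, nTrials - k + spec@beta) -
          lbeta(spec@alpha, spec@beta)))
}
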