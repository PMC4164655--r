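# mcfractal

Wavelet-transform modulus maxima (WTMM) analysis of microcalcification
clusters in grayscale lesion images, for researchers studying computational
mammography and multiscale image statistics.

Clusters of microcalcifications are often the only mammographic sign of an
early breast tumor, and the *geometry* of a cluster is informative: benign
clusters tend to sit on Euclidean supports (lines, sheets) while malignant
ones grow branching, fractal supports. `mcfractal` implements the full
chain from image to verdict:

1. **Scale space** — the gradient-of-Gaussian wavelet transform
   `T(b, a) = a ∇(φ_a * f)(b)`, whose modulus maxima trace image edges at
   every scale `a`.
2. **Skeleton** — maxima chains, their local maxima (WTMMM), and the
   space-scale lines obtained by linking them across scales. Along each
   line the modulus follows `M(a) ≈ K a^h`; the Hölder exponent `h` and
   prefactor `log2 K` are fitted per line.
3. **Detection** — a threshold gate on `(h, log K)` separates
   microcalcification-like lines (`h ≤ 0`: point-like, decaying response)
   from tissue texture (`h ≈ 1/3` fatty, `≈ 2/3` dense).
4. **Singularity spectrum** — canonical (Boltzmann-weight) multifractal
   formalism on the detected subset: `τ(q)`, `h(q)`, `D(q)` and the
   support dimension `D_F = D(q = 0)`, the per-view fractal dimension.
5. **Two-view verdict** — each case is the point `(D_CC, D_MLO)`; the
   "fractal zone" (square `[1.2, 1.8]²` plus four triangles reaching the
   Euclidean dimensions 1 and 2) flags fractal, malignant-like geometry,
   and non-fractal cases are subtyped LINE or SHEET.
6. **Bayesian layer** — Beta prior from the BI-RADS score composition
   (method of moments, sd 0.25), conjugate updating, 95% highest-density
   intervals, and 100 000-draw posterior-predictive checks.

Seeded generators for fractional Brownian tissue backgrounds, bright
compact spots, diffusion-limited aggregates and projected 3D point models,
plus an independent box-counting dimension oracle, make every stage
testable without clinical data.

## Worked example

A two-view case built from a known fractal support (a diffusion-limited
aggregate in a random 3D plane, viewed from two directions 45° apart):

```r
library(mcfractal)

pts <- generateManifoldPoints("CLUSTER", 1500, jitter = 0.002, seed = 53)
B   <- attr(pts, "basis")
mk  <- function(view, seed) {
  pr <- projectAndRasterize(pts, view = view, size = 512,
                            amplitude = 1, radius = 1.5)
  GrayImage(pr$image@.Data +
            0.01 * generateFbmSurface(1/3, 512, seed)@.Data)
}
cc  <- mk(B[, 3], 54)
mlo <- mk(cos(pi/4) * B[, 3] + sin(pi/4) * B[, 2], 55)

res <- runCaseAnalysis(cc, mlo, caseId = "demo",
                       gate = detectionGate(hMax = NA, logKMin = -4),
                       scaleGrid = defaultScaleGrid(cc, nScales = 40,
                                                    aMin = 1.5))
res$classification
#> Case demo: (D_CC, D_MLO) = (1.422, 1.534) -> FRACTAL
```

Both views measure a support dimension near 1.5 — the non-integer
signature of a branching cluster — so the case lands inside the fractal
zone. The ground-truth check: `boxCountingDimension()` on the projected
point positions gives 1.53 for the face-on view, within 0.2 of the WTMM
estimate. A line-shaped cluster instead yields dimensions near 1 in both
views and the verdict `EUCLIDEAN / LINE`.

The Bayesian companion analysis, from the study composition
(59 cases: BI-RADS scores 3/4/5 split 1/47/11; 23 of 25 malignant cases in
the fractal zone, 30 of 34 benign cases in the Euclidean zones):

```r
prior <- betaFromMeanSd(biradsPriorMean(c(1, 47, 11), 59), 0.25)
betaHdi(posteriorUpdate(prior, 23, 25))
#> 95% HDI: [0.7418, 0.9748]
```

With 95% credibility, between 74% and 97% of fractal-zone lesions are
malignant under this model.

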