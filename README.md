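# fibermosaic

Quantitative analysis of the spatial organization and distribution of muscle
fiber types (and other labeled 2-D point patterns).

Histochemical staining of a muscle cross-section yields, for each fiber type
(slow, intermediate, fast), the (x, y) coordinates of the fiber centroids.
Two questions follow. *How is each type organized* — spread uniformly, or
clustered over the fascicle? And *how differently are two types distributed*
across the same section? `fibermosaic` answers both with two complementary
tools:

**Distribution functions with RKHS dissimilarity quantifiers.** A uniform
N × N grid is laid over the (centered) point set; each occupied cell
C<sub>ij</sub> contributes a Gaussian kernel
φ<sub>ij</sub>(z) = exp(−½ (z − z̄<sub>ij</sub>)ᵗ Σ<sub>ij</sub>⁻¹
(z − z̄<sub>ij</sub>)) built from the cell's centroid and sample covariance
(with explicit rules for empty, single-point and rank-deficient cells). The
*distribution function*

Φ(z) = Σ<sub>ij</sub> R<sub>ij</sub> φ<sub>ij</sub>(z),  R<sub>ij</sub> = cell count,

is a smoothed cell histogram living in a finite-dimensional inner-product
space. Building all functions to be compared on one shared grid with pooled
per-cell covariances (`build_batch()`) places them in the *same* space, where

* distance d = ‖Φ<sub>a</sub> − Φ<sub>b</sub>‖,
* angle θ = arccos(⟨Φ<sub>a</sub>, Φ<sub>b</sub>⟩ / (‖Φ<sub>a</sub>‖ ‖Φ<sub>b</sub>‖)), and
* normalized distance D = d / (1 + d)

quantify how dissimilar two spatial distributions are (θ < 45° reads
"similar", θ > 45° "dissimilar").

**Fractal organization via the correlation method.** Each set pixel of a
binary fiber image is surrounded by square windows of growing side
ε = 2i + 1 and the mean per-window count N(ε) is fitted with the generalized
correlation law

N(ε) = a ε<sup>D</sup> + c,

by nonlinear least squares (`fit_fractal()`). D is the correlation (fractal)
dimension — D ≈ 2 uniform filling, 1 < D < 2 clustered organization, D ≈ 0
point-like; the pre-form factor a confirms a fractal pattern only for
0.1 < a < 4; the offset c absorbs small-scale deviations; fit quality is the
correlation ratio R²\* between observed and fitted curves.

The package also ships the synthetic validation geometries (ball, ring, sum,
cross) used to challenge the quantifiers, and the orchestration to rerun that
experiment end to end.

## Worked example

```r
library(fibermosaic)

# two synthetic geometries: an annulus and a disc, Q = 1000 raw points each
ring <- synth_shape("ring", Q = 1000, seed = 11)
ball <- synth_shape("ball", Q = 1000, seed = 12)

# one shared inner-product space, N = 11 grid
b <- build_batch(list(ring = ring, ball = ball), N = 11)
#> df_batch: 2 distribution functions on a shared 11x11 grid
#>   ring              303 points
#>   ball              799 points

dissimilarity(b$dfs$ring, b$dfs$ball)
#> distance d        : 80.2380
#> angle (degrees)   : 66.7170  [dissimilar]
#> normalized D      : 0.9877

# fractal organization of the disc scatter
fit <- fit_fractal(correlation_curve(rasterize_points(ball)))
fit
#> Fractal correlation fit (generalized model): N = a * eps^D + c
#>   a = 0.11   D = 1.793   c = -0.1904   R2* = 1.0000
#>   verdict: fractal; distributed in clusters over the space (1 < D < 2)
```

The 303 of 1000 ring points are those landing in the annulus; the angle of
67° says the two geometries have clearly distinct spatial distributions, and
the normalized distance is near its upper bound because both sets carry
hundreds of points. The disc scatter fits the correlation law almost
perfectly (R²\* ≈ 1) with a dimension below 2, reflecting the finite,
granular point pattern rather than a filled disc.

For fascicle data, `run_fiber_analysis()` takes CSV tables (`x,y,label`) and
returns the pairwise type dissimilarities and per-type fractal fits;
`compare_groups()` runs the normality-screened two-sample comparison between
experimental conditions. A thin command-line front end with `generate`,
`compare`, `fractal` and `experiment` subcommands lives in
`inst/cli/fiberscape.R`.

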