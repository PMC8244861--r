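---
title: "Measuring joint color/form coding with second-order representational similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring joint color/form coding with second-order representational similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaform)
```

## The question and the statistic

A visual system can encode the color and the shape of an object
*orthogonally* — the representational geometry of color is the same
whatever the object — or *interactively*, with color coding that depends on
the form it is painted on. chromaform quantifies where a layered model sits
on that continuum, layer by layer.

The unit of analysis is the **color space** of one object in one layer: the
object is rendered in 12 calibrated hues, the layer's response pattern to
each hue is extracted, and the 12×12 matrix of pairwise Pearson
correlations among those patterns (the color RSM) is vectorized to its 66
strict-upper-triangle values. Orthogonal coding predicts that any two
objects' color-space vectors correlate near +1; interactive coding pushes
the between-object correlation toward 0. The package computes, per layer:

* the mean pairwise between-object color-space correlation \(\bar r\);
* the normalized within-object color distance
  \(d = \|z_i - z_j\|_2 / (2\sqrt{n})\), averaged over the 66 hue pairs,
  which measures how *strongly* color is represented at all (0 = the hues
  are indistinguishable, 1 = antipodal patterns);
* cross-layer profiles (one object's color space correlated across layers,
  anchored at the first or penultimate layer, Fisher-z transformed before
  slope regression);
* the stability of the between-object similarity structure across layers,
  and the correlation between form similarity (grayscale responses) and
  color-space similarity.

Hierarchy trends are summarized by regressing each object pair's
between-object correlation on `layer_fraction` (1-based layer position over
total modules), first through penultimate layers only — the classification
layer pools information for labeling rather than further transforming it —
and testing the resulting slopes against zero with a one-sample t.

## Stimulus calibration

Hue must be the only thing that varies across the 12 recolorings, so all
stimuli are equated in mean luminance and mean saturation over their
non-background pixels. In CIELUV (sRGB, D65; the white point is taken as
the exact XYZ of RGB (1,1,1) under the sRGB primaries so grays are exactly
achromatic), saturation is chroma \(\sqrt{u^2+v^2}\). Calibration shifts
each masked channel (L, then chroma) by a constant to the target mean; if
any pixel then leaves its permissible range, deviations about the mean are
multiplied by the largest admissible shrink factor in (0, 1], which has a
closed form (the feasible set is an interval), keeping the mean exactly on
target. Hues are produced by rotating every pixel's (u, v) by 12 angles 30°
apart; grayscale versions set u = v = 0.

Default targets are L\* = 65, chroma = 35. The source study never prints
its converged targets; at L\* = 65 the sRGB gamut admits chroma ≈ 51 at the
worst hue, so 35 leaves headroom for textured images whose per-pixel chroma
varies around the mean. Both are configurable.

The **synthetic HSV** control parameterization is defined directly over RGB
with operations a convolution can implement: luminance = mean(R, G, B),
saturation = Euclidean RGB distance to the equal-luminance gray, hue = the
angle on the resulting iso circle with 0° at the point of maximal R,
increasing toward G. Composition is exact pre-quantization; the maximal
in-cube saturation at luminance \(l\) is \(\min(l, 255-l)\sqrt{3/2}\).

Oriented bars (defaults: 400 px canvas, 300×60 bar, 12 orientations at 15°
steps — orientation is periodic with period 180°, so the duplicate endpoint
is excluded) are drawn analytically by a point-in-rotated-rectangle test,
never by raster rotation, which keeps pixel areas equal across orientations
to well under 1% at the default geometry. Background pixels are classified
near-white at a channel threshold of 250, tolerant of JPEG speckle.

## The synthetic population generator

Real pretrained networks cannot ship with the package, so every metric is
validated on populations with known ground truth. Unit \(u\)'s response to
hue \(c\) (angle \(\theta_c\)) on object \(f\) is

\[
r_u(c,f) = (1-\lambda)\,[\alpha_u \cos(\theta_c - \phi_u) + \beta_u \xi_{uf}]
 + \lambda\, \gamma_{ucf} + \varepsilon,
\]

all tuning draws i.i.d. centered Gaussians (sd `tuning_sd` = 1), \(\phi_u\)
uniform, \(\varepsilon\) Gaussian noise (`noise_sd` default 0.25, modest
measurement noise relative to tuning). \(\lambda \in [0,1]\) is this
package's operationalization of interaction strength — the literature
offers no quantitative definition. Cosine hue tuning (rather than
unstructured color tuning) gives the additive component a shared,
form-independent color geometry, the synthetic analogue of the elliptical
early-layer hue structure real first layers show; unstructured additive
tuning would make the first-order RSM flat and the second-order correlation
ill-conditioned. At \(\lambda = 0\) every object's expected color RSM is an
affine function of \(\cos\Delta\theta\), so between-object correlations
approach 1; at \(\lambda = 1\) color tuning is redrawn per object and the
expectation is 0.

A *trajectory* (one synthetic "network") draws the additive base
\((\alpha, \phi, \beta, \xi)\) once from the master seed and shares it
across layers, redrawing only \(\gamma\) and \(\varepsilon\) per layer
under per-layer sub-seeds. This mirrors the fact that the layers of one
network transform a common upstream signal; fully independent per-layer
populations would add a layer-common fluctuation to every object pair's
correlation, which is both unrealistic and maximally anticonservative for
the slope test.

What a green synthetic test does **not** establish: that real textured
objects, real architectures, or trained weights behave like these
populations. The generator has no spatial structure, no texture statistics,
no training-induced feature selectivity, and Gaussian (not rectified,
sparse, or heavy-tailed) responses.

## Known limitation: the pair-slope t test is anticonservative

The slope inference treats the \(\binom{20}{2} = 190\) object-pair slopes
as independent observations, exactly as the source procedure describes.
They are not: pairs sharing an object share that object's sampling noise.
Monte Carlo on constant-\(\lambda\) trajectories shows the null t statistic
has standard deviation ≈ 4 rather than 1, so nominal p values are badly
anticonservative and a strict null-calibration check at α = .001 fails for
this statistic in any population of this family. The package reports the
procedure as defined (raw p values, no correction); users needing
calibrated inference should permute object labels or subsample disjoint
pairs. The corresponding acceptance check is deliberately left failing
rather than silently replaced by a different statistic.

## Numerical choices

* Population (divisor-n) z-scoring in the within-object distance makes
  \(\|z\| = \sqrt n\) exact and the identity
  \(d_{ij} = \sqrt{(1-r_{ij})/2}\) hold to 1e-10, so the [0, 1] bound is
  exact.
* Off-diagonal vectorization is the strict upper triangle, row-major; each
  pair counted once.
* Correlation inputs with variance below 1e-12 raise a degenerate-input
  error instead of returning an unstable value.
* Out-of-gamut pixels at the final LUV→RGB step are clipped channel-wise
  and counted; the count travels with the stimulus audit.
* Fisher z errors at |r| ≥ 1 unless an explicit clamp at 1−1e-7 is
  requested (the cross-layer machinery requests it, since anchor layers
  correlate with themselves at exactly 1).
* MDS is metric stress majorization (SMACOF) initialized from classical
  scaling, hence deterministic; the seed only enters the fallback random
  initialization for degenerate classical solutions.
* The greedy dissimilar-subset selection is worst-out elimination; an
  exhaustive search is exposed for small candidate sets and agrees with the
  greedy route on the test cases.
* Toy-network inputs are box-filter resized to 64×64; evaluation is pure R,
  single-threaded, and bit-deterministic given the weight seed.

## Scaled-down defaults

Desk-scale runs use 12 bar "objects", one toy network, and 10-seed
Monte Carlo averages where the source analyses used 50 objects, five large
architectures, and 100 random initializations. The pipeline exposes the
full-scale settings as configuration; nothing in the code depends on the
scale except run time.
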