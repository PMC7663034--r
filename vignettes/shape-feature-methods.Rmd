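---
title: "Shape-feature methods: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-feature methods: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmNodule)
```

This vignette records the scientific model behind `gmNodule`, the
conventions every formula relies on, and the numerical decisions that are
not obvious from the API — including their measured error.

## 1. The measurement model

A nodule is represented by a closed boundary polygon in pixel coordinates.
Everything downstream is a functional of that polygon:

- $A_n$, $P_n$ — shoelace area and arc-length perimeter;
- $A_c$, $P_c$ — area and perimeter of the convex hull;
- $L_{MA}$ — the **major axis**, the longest chord between any two
  boundary points; $L_{ma}$ — the longest chord perpendicular to it
  (within a ±2° tolerance);
- the area centroid, the orientation of the major axis, and axis-aligned
  width $W$ / depth $D$.

From these come 19 geometric descriptors (ratios such as convexity
$P_c/P_n$, solidity $A_n/A_c$, compactness $4\pi A_n/P_n^2$, roundness
$4\pi A_n/P_c^2$, eccentricity $L_{ma}/L_{MA}$, the circular and elliptic
variances of the radial profile) and 8 morphological ones (area,
perimeter, aspect ratio $D/W$, AP ratio $A_n/P_n$, and perimeter ratios
and differences against a *related ellipse* with semi-axes
$L_{MA}/2, L_{ma}/2$ and a *relevant circle* of equal area).

Several exact identities follow and are enforced at $10^{-9}$ relative
tolerance in the test suite; they make most coding mistakes in any one
feature loudly inconsistent with the rest:

$$\text{compactness} = \text{roundness}\cdot\text{convexity}^2,\quad
\text{tcp\_ratio} = \text{compactness}^{-1/2},$$
$$\text{eccentricity}\cdot\text{axis\_ratio} = 1,\quad
\text{ap\_ratio}\cdot P_n = A_n,\quad
\text{bounding\_box} = L_{MA}\cdot L_{ma}.$$

### Pixel and angle conventions

Pixel $(i, j)$ (0-based) occupies $[i, i{+}1)\times[j, j{+}1)$ and has
center $(i{+}0.5,\ j{+}0.5)$; a contour with integer vertices around a
$w\times h$ pixel block therefore encloses exactly $wh$ pixel centers.
Contours are x-right/y-down (image convention); orientation is converted
to the y-up frame and reported in degrees in $(-90, 90]$. The aspect ratio
is axis-aligned depth over width, so values above 1 mean taller-than-wide
— the malignancy-associated sign.

## 2. Numerical choices and their measured error

**Mask tracing (σ = 0.9 Gaussian pre-blur).** Tracing a binary mask at the
0.5 level of the raw pixel grid yields a staircase whose perimeter
overestimates a digitized disk of radius 50 by more than 5%. Instead the
mask is zero-padded, blurred with a Gaussian of σ = 0.9 px, and the 0.5
level set is extracted by marching squares: for a straight edge the 0.5
crossing of the blurred step sits exactly on the true edge, so the
staircase vanishes at sub-pixel cost elsewhere. Measured on the digitized
disk: perimeter +0.75%, area +0.04%, maximum radial deviation 0.27 px,
and a contour→mask→contour round trip with Jaccard overlap ≈ 1.0. Setting
`traceSigma = 0` in `maskToContour()` recovers the raw polygon.

The residual limitation is curvature: the blur displaces the level set
inward by roughly $\kappa\sigma^2/2$ at curvature $\kappa$, so features of
extremely spiculated shapes carry an irreducible ~2% raster-to-contour
discrepancy at the default canvas scale. A curvature-compensating
correction was evaluated and rejected: it amplifies vertex noise and makes
the worst case worse.

**Axis searches on a densified boundary.** Sparse polygon annotations
(e.g. a 4-vertex rectangle) have no perpendicular chord between vertices
at all, so the boundary is densified to ~1 px vertex spacing (capped at
2000 points) before the $O(N^2)$ chord searches. The production search is
tested for *exact* equality against an independent brute-force scan,
including the lexicographic tie policy. For the 40×20 rectangle this gives
$L_{MA} = \sqrt{2000} = 44.72$ and $L_{ma} = 22.36$ px (the longest chord
perpendicular to the diagonal), both matched to machine precision.

**Radial profiles on equal-arc-length resamples.** Circular and elliptic
variance are statistics of boundary samples. Sampling at ~1 px spacing
makes them depend on image scale — catastrophically so for the elliptic
variance, which is near zero on smooth ellipses, where sampling jitter
dominated the value itself. The profiles are therefore computed on 720
samples at equal arc-length fractions, a parametrization-level rule that
is exactly equivariant under scaling and rigid motions. Measured worst
deviation over 50 generated shapes: 0.18% under 2× scaling (residual from
the axis search), ~10⁻¹⁵ under 90° rotation, 0.01% under mirroring.

**Ellipse perimeter.** Ramanujan's second approximation, which agrees with
numeric arc-length quadrature to better than 0.1% for all aspect ratios up
to 4 (tested); nodule-like shapes sit far below that.

**Split criterion.** `ForestConfig()` records
`splitCriterion = "entropy"`; the `ranger` backend implements Gini
impurity for classification. The two criteria choose identical splits in
the overwhelming majority of cases, and the package records the requested
criterion rather than silently renaming it.

## 3. The synthetic shape generator

`generateShape()` draws a star-shaped polygon in polar form about the
canvas center:

$$r(\theta) = r_e(\theta)\,\bigl(1 + \lambda\sin(3\theta + \phi)
  + \alpha\, s(\theta)\bigr)$$

with $r_e$ the radius of a rotated base ellipse, $\lambda$ a smooth
three-lobe lobulation, and $s(\theta)$ seeded band-limited noise (three
harmonics centered on the requested spicule count, normalized to unit
peak) scaled by the spicule amplitude $\alpha$. Because $r > 0$ for all
$\theta$, the contour can never self-intersect; amplitudes that would
drive $r$ toward zero are rescaled with a warning.

`generateCohort()` samples class-conditional parameters:

| parameter | benign-like | malignant-like |
|---|---|---|
| depth/width ratio | U(0.55, 0.9) — wider than tall | U(1.05, 1.5) — taller than wide |
| horizontal semi-axis (px) | U(35, 60) | U(30, 50) |
| rotation (deg) | U(−15, 15) | U(−10, 10) |
| spicule amplitude | U(0, 0.03) | U(0.08, 0.2) |
| lobulation amplitude | U(0, 0.02) | U(0.03, 0.08) |
| TIRADS category | 2 or 3 | 4a/4b/4c/5 |

These encode the standard sonographic malignancy attributes (orientation,
margin irregularity, lobulation) as *geometry*. They deliberately make the
classes separable: the generator exists to exercise and validate the
pipeline end to end, not to emulate ultrasound. In particular it models no
echotexture, no acoustic shadowing, no annotation noise, and no
intermediate-risk overlap between classes — so near-perfect classification
metrics on synthetic cohorts indicate a working pipeline, not clinical
performance. The label-permutation control (accuracy ≈ 0.5) guards against
pipeline leakage rather than optimistic bias in the features.

## 4. Problem sizes and reproducibility

The shipped experiment scale — 400 cases per class, a 70–30 stratified
split and a 400-tree forest; and cohort balancing from a 17/82 split to
1594 rows per class (3188 total) — was chosen so the full pipeline runs in
a few minutes on one CPU while remaining large enough for stable metrics.
All stochastic stages (generator, augmentation, split, forest) consume
seeds explicitly; the same seeds reproduce cohorts byte for byte, which
the tests verify with `identical()`.

```{r example}
sh <- generateShape(ShapeSpec(baseSemiAxes = c(50, 35), rotationDeg = 10,
                              spiculeAmplitude = 0.12, seed = 3))
v <- featureValues(extractFeatures(sh$contour))
round(unlist(v[c("solidity", "compactness", "aspect_ratio")]), 4)
```
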