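---
title: "Quantifying tip growth: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tip growth: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipgrow)
```

## The problem

Tip-growing plant cells -- root hairs, rhizoids, pollen tubes, zygotes --
elongate at a single apex. Quantifying that growth from time-lapse
microscopy requires an objective definition of the cell tip: the cell as
a whole drifts and rotates between frames, the apex is a smooth cap with
no landmark, and intracellular signals (nucleus, microtubule bands) are
only interpretable in a coordinate system attached to the cell, not to
the stage. `tipgrow` implements a complete pipeline:

1. **Segmentation** to one binary mask per frame (global Otsu threshold,
   or externally generated masks, e.g. from a promptable deep-learning
   segmenter);
2. **Contour extraction** at subpixel resolution;
3. **Coordinate normalization**: a rigid transform per frame that
   maximizes a normalized image correlation against a reference frame;
4. **Centerline** by Voronoi-tessellation skeletonization with branch
   pruning, and **tip/bottom detection** by linear extrapolation of the
   centerline to the cell edge;
5. **Kinematics**: tip velocity $dL/dt$ (with $L$ the arc length of the
   centerline from bottom to tip) and growth direction $\Delta\theta$
   (signed angle of the tip displacement against a reference axis);
6. **Signal profiling**: arc-length intensity profiles, kymographs, and
   truncated-Gaussian band fits giving the position $\mu$, width
   $\sigma$, and "upper/lower ends" $\mu \pm \sigma$ of a fluorescent
   band.

## Models and estimators

### Coordinate normalization

Frame $t$ is aligned to a reference by the rigid transform
$(u, v, \theta)$ (translation in px, rotation about the frame center)
maximizing

$$\gamma(u,v,\theta)
  = \frac{\sum_{x,y}\,(f_\mathrm{ref} - \bar f_\mathrm{ref})
                     (f_t^{(u,v,\theta)} - \bar f_t)}
         {\sqrt{\sum (f_\mathrm{ref}-\bar f_\mathrm{ref})^2
                \cdot \sum (f_t^{(u,v,\theta)}-\bar f_t)^2}},$$

where $f_t^{(u,v,\theta)}$ is the frame rotated by $\theta$ and shifted
by $(u,v)$ with bilinear interpolation, pixels falling outside the frame
set to 0, and the bars denote spatial means over the full frame. The
optimizer is an exhaustive integer grid (default $\pm 15$ px /
$\pm 15^\circ$), accelerated by a block-averaged coarse level, followed
by three levels of half-step bisection (final resolution 0.125 px /
0.125°). By default frames are registered successively ($t$ against
$t-1$) and the transforms composed: consecutive frames differ minimally
even while the cell grows. Direct-to-reference registration is available
(`strategy = "direct"`).

Two properties of $\gamma$ deserve explicitness:

* **Affine intensity invariance.** $\gamma$ is exactly invariant under
  $I \mapsto aI + b$ ($a > 0$) when no zero-fill is involved (identity
  transform), and under pure rescaling $aI$ in general. A nonzero offset
  $b$ does not commute with the zero-fill convention, so invariance
  under full affine maps is only approximate at nonzero transforms.
* **Axial degeneracy of straight tubes.** A uniform straight tube is
  nearly translation-invariant along its own axis. While the cell grows,
  $\gamma$ develops a plateau of width comparable to the per-frame
  growth, and its maximum genuinely sits at a partial
  growth-compensating shift. The grid search therefore prefers the
  smallest transform among near-ties (tolerance $10^{-4}$), and
  refinement requires a real improvement ($>10^{-7}$). For cells with
  visible curvature or texture the optimum is well identified; for
  perfectly straight featureless cells the axial component of the
  normalization should not be over-interpreted, and registration can be
  disabled (`normalize = FALSE`) when the cell base is fixed
  experimentally.

### Voronoi skeletonization and the centerline

The contour polygon (marching-squares iso-contour of the mask at level
0.5, resampled to 1 px spacing) is treated as a point cloud. Voronoi
vertices of that cloud that fall strictly inside the polygon approximate
the medial axis; Voronoi edges whose endpoints are both interior connect
them into a skeleton graph. Implementation notes that matter
numerically:

* Uniformly resampled boundaries contain many exactly cocircular
  4-point configurations, which are degenerate for any Delaunay
  algorithm. The triangulation runs on normalized coordinates with a
  deterministic $\sim 10^{-5}$ jitter that only disambiguates topology;
  circumcenters are computed from the unjittered coordinates.
* Twin Voronoi vertices closer than 0.02 px (the two circumcenters of a
  formerly cocircular quad) are merged, and the graph is reduced to its
  minimum spanning tree: the medial axis of a simple polygon is a tree,
  so residual cycles are numerical artifacts.

Leaf branches shorter than `min_branch_length` are pruned iteratively.
The default threshold is $1.2\times$ the median distance of skeleton
nodes to the contour: that distance estimates the half-width, spur
branches caused by boundary noise are shorter than the half-width, and
branches inside a semicircular end cap are up to exactly one half-width
long -- hence the 1.2 factor, so that cap branches fall below the
threshold while the axis (which is at least $2.2\times$ the width in any
elongated cell) cannot be consumed. The centerline is the longest
remaining geodesic between two leaves, with a deterministic
lexicographic tie-break.

### Tip and bottom detection

The Voronoi skeleton cannot reach the cell edge (its clearance stays
about one half-width). Each end of the pruned path is extended by a
total-least-squares line fitted through its terminal points; the
tip/bottom is the first intersection of that ray with the contour. Three
conditioning steps control the error of this extrapolation, which is
amplified by the half-width-long lever arm:

* the path is resampled at 1 px and the fit window grows from `k`
  (default 5) points to the local half-width, so direction noise
  averages out on wide cells; the ray direction is the mean of this
  window fit and a short fit on the smoothed body end (the window fit
  lags the end tangent of a curving axis, the short fit is noisier --
  their failure modes are complementary);
* terminal points whose boundary clearance is below $0.92\times$ the
  body half-width are trimmed first -- they are residual stubs of cap
  branches curving toward boundary corners, not medial-axis points;
* the path body between the two fitted ends is smoothed by locally
  *quadratic* loess against arc length (`smooth_span = 0.2`). The
  discrete Voronoi path zigzags at the contour-sampling scale, which
  inflates its arc length (hence $L$ and $dL/dt$) by a few percent;
  degree-2 local fits remove the zigzag without biasing the end tangent
  of a bent cell, which a locally linear smoother does (it cost up to
  3 px of tip error in development). Contour smoothing, by contrast, is
  OFF by default.

### Kinematics

$dL/dt$ uses the forward difference of the arc length $L$, not the
Euclidean tip displacement, so velocity means elongation of the cell
axis. $\Delta\theta$ is the signed angle from a reference axis (default:
bottom-to-tip direction of the first frame) to the displacement of the
tip between consecutive frames, computed after flipping the image y-axis
so that positive angles are counterclockwise on a screen-up display;
zero displacements carry the previous angle forward and set a flag. Two
identities are enforced by construction and verified in the tests:
$\sum_t dL/dt \cdot \Delta t = L_\mathrm{end} - L_\mathrm{start}$, and
rigidly rotating the whole sequence by $\phi$ shifts every
$\Delta\theta$ by $-\phi$ (mod 360°).

### Band fitting

Intensity profiles are sampled along the local normal of the centerline
(default half-width: 40% of the local cell width; mean across the
cross-section, max by flag) on an arc-length grid from the bottom
($s = 0$) to the tip ($s = L$). The band model is
$I(s) \approx B + A \exp(-(s-\mu)^2 / 2\sigma^2)$, fitted by bounded
least squares (L-BFGS-B) *restricted to a window* -- that is what
"truncated" means here; the data are intensities, not a probability
density, so no renormalized truncated likelihood is involved. The auto
window is $\hat\mu_0 \pm 3\hat\sigma_0$ with moment-free initialization
($\hat\mu_0$ = argmax, $\hat\sigma_0$ from the FWHM). Band "ends" are
reported as $\mu \pm k\sigma$ with $k = 1$ by default and exposed,
because published kymograph overlays draw such lines without a stated
formula; any quantitative use should state $k$. Frame-to-frame tracking
initializes each window from the previous fit ($\mu \pm 4\sigma$) and
marks failed frames as missing without disturbing their neighbors.
Kymographs mark bins beyond a frame's $L$ as `NA`, never 0, since 0 is a
valid intensity.

## The synthetic generator and what a green test establishes

`make_growing_cell()` renders a capsule -- a constant-width tube around
a growing axis polyline with semicircular caps -- analytically: pixel
intensity ramps linearly across a one-pixel band at the boundary (an
idealized point-spread), so contours are subpixel-consistent and
unbiased by rasterization. Defaults describe a root-hair-like recording:
0.2 µm/px, 10-min frames, 3 µm width, 12 µm initial length, growth at
0.2 µm/min (the fast end of reported root-hair rates; rhizoids reach
about 0.6 and zygotes 0.05 µm/min), per-frame rigid jitter (SD 2 px,
1.5°) about the frame center, additive Gaussian noise (SD 5 on a 10/200
background/foreground scale), and optionally a Gaussian intensity band
(σ = 2 µm) in a second channel, placed at a fixed fraction of $L$ or a
fixed offset from the tip.

What the generator does *not* emulate: realistic point-spread functions
and shot noise, intensity inhomogeneity inside the cell, neighboring
cells and debris, focus drift, and deformable (non-rigid) cell motion. A
green suite therefore establishes the geometry and estimator chain on
idealized single cells with known ground truth; it does not certify
segmentation quality on real micrographs, which is why external masks
are a first-class input.

## Verified accuracy (recomputed by the test suite and `scripts/acceptance.R`)

On 20 seeded capsules per seed (widths 10--40 px, lengths 60--300 px,
bends up to 30°): tip endpoints within 1.5 px of ground truth and $L$
within max(2 px, 2%); rigid-jitter recovery with median error well below
(0.5 px, 0.5 px, 0.5°); programmed growth rates recovered by median
$dL/dt$ within 10%; noise-free Gaussian band parameters within 1% and,
under 5% amplitude noise over 20 seeds, median $|\hat\mu - \mu|$ < 0.5 µm
with bias < 0.1 µm; tip-anchored kymographs of a tip-fixed band flat to
< 2 bins; the pruned Voronoi centerline within 1 px (mean) of the
independent distance-transform ridge; and byte-identical outputs under a
fixed configuration and seed.

## Known limitations

* Single cell, single tip: multi-tip cells and touching cells are out of
  scope.
* The axial component of the normalization is weakly identified for
  perfectly straight, featureless cells while they grow (see above).
* The smallest supported contour-smoothing span is 0.02; heavier
  smoothing that self-intersects falls back automatically with a
  warning.
* The bundled TIFF codec reads/writes uncompressed grayscale baseline
  TIFF (8/16-bit unsigned, 32-bit float) only; compressed or RGB stacks
  must be converted first.
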