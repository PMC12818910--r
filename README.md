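# tipgrow

Quantification of tip-growth dynamics in plant cells from 2-D time-lapse
microscopy: root hairs, rhizoids, pollen tubes, zygotes — any cell that
elongates at a single apex.

Tip-growing cells drift and rotate between frames, their apex is a smooth
featureless cap, and intracellular signals are only meaningful in a
coordinate system attached to the cell. `tipgrow` addresses all three:

- **Centerline by Voronoi skeletonization.** The subpixel cell contour is
  treated as a point cloud; interior Voronoi vertices approximate the
  medial axis. Short branches are pruned and the longest remaining
  geodesic is the cell axis.
- **Objective tip/bottom detection.** The skeleton cannot reach the cell
  edge, so each end is extended by a total-least-squares line through its
  terminal points; the tip (and bottom) is where that ray meets the
  contour.
- **Coordinate normalization.** Each frame is rigidly aligned
  (translation *u, v*, rotation *θ* about the frame center) by maximizing
  the normalized correlation

  γ(u,v,θ) = Σ (f_ref − f̄_ref)(f^(u,v,θ) − f̄) / √(Σ (f_ref − f̄_ref)² · Σ (f^(u,v,θ) − f̄)²),

  with out-of-frame pixels set to 0 — exhaustive grid search plus
  bisection refinement.
- **Kinematics.** Tip velocity dL/dt, with L the arc length of the
  centerline from bottom to tip, and growth direction Δθ, the signed
  angle of the tip displacement against a reference axis (positive =
  counterclockwise on screen).
- **Signal profiling.** Arc-length intensity profiles, bottom- or
  tip-anchored kymographs, and truncated-Gaussian band fits
  I(s) ≈ B + A·exp(−(s−μ)²/2σ²) on a restricted window, reporting the
  band center μ, width σ, and ends μ ± σ (nucleus position, microtubule
  band).

A synthetic-movie generator with exact ground truth (analytic capsule
rendering, seeded rigid jitter and noise, optional Gaussian band channel)
makes every stage testable offline, and a minimal multi-page TIFF
reader/writer removes any imaging-package dependency.

## Worked example

```r
library(tipgrow)

spec  <- synthetic_cell_spec(band_center_rel = 0.6, seed = 1)  # root-hair-like movie
movie <- make_growing_cell(spec)
movie$seq
#> <image_sequence> 8 frame(s), 220 x 160 px, channels: main, signal
#>   pixel_size = 0.2 um/px, dt = 10 min

cfg <- run_config(input = movie$seq,
                  bottom_anchor = c(movie$truth$table$bottom_x[1],
                                    movie$truth$table$bottom_y[1]),
                  outdir = "demo_out")
res <- run_pipeline(cfg)
round(res$trace[, c("frame", "time", "L_um", "dLdt", "delta_theta_deg")], 3)
#>  frame time   L_um  dLdt delta_theta_deg
#>      0    0 12.055    NA              NA
#>      1   10 14.015 0.196          14.523
#>      2   20 16.014 0.200           1.847
#>      3   30 17.998 0.198           1.375
#>      4   40 20.011 0.201           3.836
#>      5   50 22.020 0.201           1.791
#>      6   60 24.013 0.199          -4.815
#>      7   70 26.009 0.200           3.924
```

The movie was generated with L(0) = 12 µm growing at 0.2 µm/min in 10-min
frames under 2-px stage jitter and camera noise: the recovered lengths
track 12 → 26 µm within a few hundredths of a micrometer and dL/dt sits
at the programmed 0.2 µm/min (Δθ fluctuates around 0 because the cell
grows straight; its scale reflects ~1 px tip localization against a 10 px
per-frame displacement). The second channel carries a Gaussian band at
0.6·L, recovered by the truncated-Gaussian tracker:

```r
round(res$band[, c("frame", "mu_um", "sigma_um", "lower_um", "upper_um", "L_um")], 2)
#>  frame mu_um sigma_um lower_um upper_um  L_um
#>      0  7.33     1.98     5.35     9.31 12.06
#>      1  8.50     2.02     6.48    10.52 14.01
#>      2  9.64     2.00     7.64    11.64 16.01
#>      3 10.87     1.99     8.88    12.85 18.00
#>      4 12.05     2.00    10.05    14.05 20.01
#>      5 13.21     2.01    11.20    15.22 22.02
#>      6 14.34     2.02    12.32    16.35 24.01
#>      7 15.66     2.01    13.65    17.67 26.01
```

(true μ = 0.6·L runs 7.2 → 15.6 µm with σ = 2 µm). `run_pipeline()` also
writes every table as CSV, the kymograph as 32-bit TIFF + CSV, plots, and
a JSON run log with the full realized configuration under
`cfg$outdir`.

Real data enter the same way: `run_config(input = "movie.tif",
signal = "nucleus.tif", masks = "masks.tif", pixel_size = 0.13, dt = 10,
bottom_anchor = c(x, y))` — masks may come from any external segmenter
(e.g. a promptable deep-learning model); without them a global Otsu
threshold is used (`polarity = "dark_object"` for bright-field).

There is also a command-line interface with `simulate`, `run`, and
`kymo` subcommands (`inst/exec/tipgrow`, or `tipgrow_cli()` from R).

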