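---
title: "Calibrating InSAR elevation to mangrove canopy height: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating InSAR elevation to mangrove canopy height: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangroveheight)
```

## The estimation problem

Over dense, low-relief mangrove forest, an X-band InSAR digital elevation
model tracks an elevation near the top of the canopy. Because mangroves grow
on terrain at essentially sea level, the geoid-referenced DEM height is
itself a first-order estimate of canopy height — but a biased one, since the
radar scattering phase center sits somewhat below the outer canopy surface.
Spaceborne waveform lidar provides sparse but accurate canopy-top
observations: each ~25 m footprint yields RH98, the height below which 98%
of the returned waveform energy accumulates. This package implements the
workflow that turns 12 m InSAR elevation tiles into a calibrated canopy
height map: harmonize vertical datums, repair gross DEM artifacts against a
coarser reference DEM, mask to mangrove extent and open water, pair lidar
footprints with DEM zonal statistics, filter the pairs hard, fit a weighted
height calibration, mitigate implausibly tall tiles, and validate against
held-out lidar and airborne laser scanning.

Every stage is exercised end-to-end on synthetic scenes, so the whole
pipeline is testable with no satellite downloads.

## The calibration model

The calibration relates footprint RH98 to the **maximum** DEM value under
the footprint (the maximum, not the mean, because the waveform metric
responds to the tallest canopy elements the footprint contains). Four
candidate forms are fitted by weighted least squares — linear, quadratic,
power (on log-log axes) and a linear regression on square-root-transformed
variables,

$$\sqrt{\mathrm{RH98}} = a\,\sqrt{\mathrm{TDX}} + b,
  \qquad \widehat{\mathrm{RH98}} = \left(a\sqrt{\mathrm{TDX}} + b\right)^2,$$

and the best is selected by hold-out-free training RMSE (ties broken by MAE,
then |bias|, then correlation). The square-root form is fitted on the
transformed variables and squared back; it is *not* fitted by nonlinear
least squares on the original scale. It dominates in practice because the
radar height deficit shrinks as canopies grow taller and denser — a concave
relationship that a square-root link captures with two parameters. For the
global product this workflow reproduces, the selected calibration is
$(1.02\sqrt{\mathrm{TDX}} + 0.33)^2$; those coefficients are used as
reference values throughout the test suite.

Height categories ([0,10), [10,20), [20,30), [30,40), [40,50), ≥50 m) serve
two purposes. First, the 70/30 training/validation split is stratified by
category (per category, `floor(0.7 n)` points train; floor rounding means a
singleton category contributes its point to validation). Second, each
observation is weighted by

$$w = \frac{1}{6\,n_c},$$

where $n_c$ is its category's training count, so each of the six categories
contributes total mass 1/6 regardless of abundance. Short mangroves
outnumber 50 m stands by four orders of magnitude; unweighted least squares
would fit the short-stature bulk and extrapolate badly into the tall tail
that matters most for carbon accounting. Weights are computed on the
training set after the split, on the regressand (RH98).

A statistical consequence worth knowing: the weighting concentrates 1/6 of
the total influence in whatever handful of points occupies the rarest
category, so the variance of the fitted coefficients is governed by the
*smallest* category count, not the total sample size, and category
assignment from noisy observed heights couples the weights to the noise near
bin edges. The test suite includes a stochastic parameter-recovery check
that measures exactly this behaviour on a scaled-down corpus.

## Quality filtering

Footprint pairs pass a fixed-order cascade; the first failing criterion is
recorded so rejection accounting is exact and reproducible. Retention
requires, in order: degrade flag 0; quality flag 1; detected modes ≥1 and
<5; reported-DEM-minus-geoid <50 m; Landsat water persistence <80;
|elevation of lowest mode − mean sea surface| <5 m; total energy in (2000,
25000); footprint max DEM in (0, 60) m; footprint min DEM <60 m; RH98 in
(0, 60) m; at least 3 DEM pixels under the footprint; and a footprint DEM
standard deviation below 1.5 m (3–4 pixels), 2 m (5–6) or 3 m (>6). All
comparisons are strict except the two ≥ bounds; the footprint standard
deviation is the sample (n−1) statistic, defined as 0 for a single pixel
(such footprints are rejected by the count rule anyway).

A final outlier stage groups the survivors into 2 m bins — half-open,
anchored at 0 — and removes pairs more than 3 sample standard deviations
from their bin mean. The rule is applied as two *marginal* passes (DEM-max
deviations within RH98 bins, RH98 deviations within DEM-max bins; a pair
removed by either is removed, with bin statistics computed once on the
input): a literal joint 2 m × 2 m binning would leave almost no within-bin
variance for a 3σ rule to act on. Bins with fewer than 3 members are exempt
(their σ is unstable). Note an intrinsic property of within-bin 3σ rules: a
single gross outlier inflates its own bin's standard deviation, and the
largest standardized deviation n points can produce is $(n-1)/\sqrt{n}$, so
bins need roughly a dozen members before a lone outlier is detectable at 3σ.

## Tall-tile mitigation

Extent misclassification lets upland forest and hillsides leak into the
mangrove mask, producing implausibly tall pixels. Tiles with any pixel above
50 m are flagged and their 99th-percentile heights (linear interpolation
between order statistics, the type-7 convention, fixed everywhere in the
package) are ordered and fitted with a 5th-order polynomial over ranks
normalized to [0, 1] for conditioning. The fitted value at the inflection of
that curve separates artifact-dominated tiles (shallow ramp of modest
percentiles) from genuinely tall canopy (steep tail). When the second
derivative has several in-range roots, the package uses the **largest**: on
the J-shaped curves these populations form, a least-squares quintic
oscillates over the shallow ramp and its earlier sign changes are fit
artifacts sitting below most of the artifact tiles, while the last root
marks the turn into the sustained convex rise. Flagged tiles whose 99th
percentile falls below the threshold are capped — every pixel above the
percentile is set to it, not just the single maximum (replacing only the
maximum would leave the second-tallest outlier untouched) — and tiles above
the threshold are left unchanged. Mitigation is idempotent and never
increases any pixel. The threshold is always recomputed from the tile
population being processed; 31.02 m is its known value for the real global
product and is deliberately not hard-coded.

## Raster handling and numerical conventions

Rasters are carried by a lightweight in-package container: a numeric matrix
with a north-up affine georeference (WGS84 geographic coordinates, pixel-is-
area), a vertical-datum tag for elevation layers, and NA-as-nodata in
memory. On disk the package uses a self-describing plain-text raster format
plus CSV for shot tables, YAML for scene configurations and JSON for fitted
models, keeping every artefact diffable and dependency-free. Nominal metric
resolutions (12, 25, 30, 1 m) are expressed in degrees at the scene
latitude; footprint geometry uses a local equirectangular approximation
(exact to well under a millimeter at 12.5 m radius).

Fixed conventions, stated once and used everywhere:

* Vertical datum: orthometric = ellipsoidal − geoid undulation; the
  undulation is consumed as a raster input, never computed.
* Artifact repair is per pixel on the absolute DEM-vs-reference difference
  (threshold 30 m); a wholesale per-tile swap would discard good data.
* Height clipping (0.1–60 m defaults) sets nodata rather than clamping:
  out-of-range pixels are ground or non-mangrove surfaces, not 60 m canopy.
* Water persistence is the fraction of *valid* stack layers at or below
  −19 dB; classification is strictly greater than 0.70, so a pixel at
  exactly 70% is land.
* Nearest-neighbor resampling assigns each target pixel the source pixel
  containing its center; rasterization labels pixel centers, with boundary
  points counted inside every touching polygon and the lowest label winning
  ties, deterministically.
* Residuals are always map minus reference; bias = mean(predicted −
  observed).
* Airborne-CHM aggregation requires ≥50% valid 1 m coverage per 12 m cell;
  per-country "median of the top 100" falls back to the median of all
  values when a country has fewer than 100 pixels.

## What the synthetic scenes emulate

The generator (`scene_config()`, `generate_scene()`) produces scenes with
the statistical structure the pipeline assumes:

* **Truth field**: smoothed Gaussian noise rescaled to the configured height
  range (default 1–50 m over a 120 px tile with a 20 px correlation length);
  any smooth positive field suffices for the pipeline's purposes. Canopy
  tapers toward channels, as fringe stands do.
* **Water**: meandering channels drawn as lateral random walks (default ~10%
  of the tile), nodata in the truth; channel pixels are persistently dark
  (≤ −19.5 dB) in every backscatter layer, land pixels ~N(−8, 2) dB.
* **DEM**: truth + undulation (constant plus a gentle east–west gradient) +
  N(0, 1 m) pixel noise + disc-shaped artifact patches of +90 m, disjoint by
  construction. The 30 m reference DEM is the block mean of the surface.
* **Shots**: footprint-mean of the truth within 12.5 m, plus N(0, 2 m)
  vertical noise and 10 m isotropic geolocation jitter; the quality fields
  of clean shots are drawn well inside the passing ranges. Exactly
  `round(contamination_fraction × n_shots)` shots fail exactly one randomly
  chosen criterion each, recorded in a `contaminated_by` ledger column so
  filter accounting is testable shot by shot. Shot positions are drawn from
  the tile interior (2 px margin — border-straddling footprints belong to
  the neighboring tile of a mosaic) and resampled until the footprint covers
  at least 3 valid pixels, since a 25 m footprint centered near a pixel-edge
  midpoint of a 12 m grid covers only 2 pixel centers; without that
  constraint a deterministic accounting of contaminated-vs-clean rejections
  would be confounded by sampling geometry.
* **Airborne CHM**: 12 × 12 one-meter pixels per cell, truth plus N(0,
  0.5 m); water cells are nodata.
* **Countries**: a two-polygon EEZ split at a meridian through the scene.

All randomness flows from a single seed; identical configurations are
bit-identical. What the scenes do **not** emulate: waveform physics and
orbital sampling geometry of the lidar, SAR speckle statistics, tides,
geolocation-error correlation along orbits, or real extent-map error
structure. Green tests therefore demonstrate that the *algorithms* are
correct and internally consistent, not that the accuracy figures obtained on
synthetic scenes transfer to real acquisitions; the real-data accuracy of
the global product (hold-out RMSE ≈ 2.4 m) cannot be reproduced without the
real tiles and footprints.

## Problem sizes and runtime choices

The default test scenes are 120 × 120 pixels (≈ 1.4 × 1.4 km) with
1000–2000 shots, chosen so a scene generates in about a second and the whole
suite, including 100-trial oracle-equivalence sweeps for the seven
vectorized kernels, runs in well under a minute. The stochastic
parameter-recovery check uses 20 seeds of 10^5 pairs. The acceptance script
(`scripts/acceptance.R`) regenerates every reported quantity from scratch at
these sizes in a few seconds.

## Known limitations

* No uncertainty propagation: the calibration yields a point prediction per
  pixel; no confidence maps.
* The weighting scheme's variance concentration in rare height categories
  (discussed above) is inherent to equal-category-mass weighting with
  heavily imbalanced data.
* The binned outlier rule cannot detect lone outliers in sparsely populated
  bins (the $(n-1)/\sqrt{n}$ bound above).
* Rasterization is center-sampling, adequate at 12 m against ~km-scale
  polygons; no area-weighted partial coverage.
* The text raster format is for pipeline interchange and testing, not a
  replacement for cloud-optimized production formats.
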