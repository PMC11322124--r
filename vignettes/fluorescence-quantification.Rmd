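---
title: "Quantifying pseudo-colored surgical fluorescence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pseudo-colored surgical fluorescence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluoroquant)
```

## The measurement model

Exoscope systems used in fluorescence-guided sentinel-lymph-node mapping
often cannot export raw near-infrared frames; the detected signal is
painted blue into an ordinary 24-bit RGB still. `fluoroquant` measures
fluorescence from that rendering under three assumptions that mirror
standardized ex-vivo imaging:

1. specimens are photographed on a clean white background at fixed
   geometry, so the background is achromatic and carries no signal;
2. fluorescence appears only as blue pseudo-color, i.e. within a hue band
   of 165–180 on the 0–255 hue scale (pure blue, 240°, maps to
   `240/360 × 255 = 170`);
3. pixel brightness in the blue channel is a monotone proxy for
   fluorescence intensity, bounded by the display range 0–255 (a genuine
   limitation of pseudo-color analysis: the dynamic range is compressed
   relative to raw NIR data, and signal below the display threshold is
   unrecoverable).

Two quantities are measured inside a node ROI after median filtering and
conversion to hue/saturation/intensity planes:

- surface fluorescence, `100 × |signal| / |node ROI|`, where the signal
  mask is the set of ROI pixels passing an inclusive hue × intensity gate;
- average fluorescence intensity (AU), the mean blue-channel value over the
  signal mask minus the background term, itself the mean blue value over
  the threshold-passing pixels of a fixed background circle
  (conventionally 5,806 px, the same circle for every image).

Because the hue of an achromatic pixel is defined as 0 — outside the blue
band — a white background can never contribute signal, and the background
term is identically zero on standardized images. The package still
measures it rather than assuming it, so deviations from standardized
conditions surface as nonzero background rather than silent bias.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| hue band | 165–180 | 0–255 hue | blue pseudo-color; 170 is pure blue |
| intensity floor | 30 (`A`/`T1`), 35 (`T2`), 45 (`B`/`T3`) | AU | 30 keeps dull dark-blue signal; 45 drops it |
| median-filter radius | 1 (3×3) | px | remove isolated noise before gating; 0 disables |
| background circle | 5,806 | px | fixed reference area on clean background |
| score bands | (0], (0,25], (25,50], (50,75], (75,100] | % | ordinal 0/1+/2+/3+/4+ scale |

All threshold bounds are inclusive, matching closed printed ranges like
"165–180". Saturation is deliberately never thresholded: adjusting it
would re-introduce the subjectivity the workflow is designed to remove.
The lenient/strict intensity-floor pair is the interesting contrast: dull,
dark-blue fluorescence (intensities in the low 30s–low 40s) passes the
30 AU floor but not the 45 AU one, which is exactly why the lenient
threshold agrees better with what observers call positive.

### Score binning for continuous percentages

The visual scale is printed in integer bands (1–25%, 26–50%, ...). A
measured percentage is continuous, so the bands are read as half-open
intervals with inclusive upper bounds: `(0, 25]`, `(25, 50]`, `(50, 75]`,
`(75, 100]`, with score 0 reserved for exactly 0%. Thus 25% scores 1+,
25.4% scores 2+, and any nonzero detection is at least 1+. The boundaries
are a `boundaries` argument of `assign_score()` for anyone preferring a
different convention.

## The synthetic-scene generator

No clinical images ship with the package (the study data behind the
workflow were never deposited), so every downstream stage is exercised on
generated scenes with exact ground truth: an elliptical node on a pure
white canvas, a controlled fraction of node pixels painted in-band at a
controlled intensity, and the true node/fluorescence masks returned
alongside the image.

Design choices, made once:

- **Pixel-subset vs blob geometry.** By default the fluorescent pixels are
  a seeded random subset of exactly `round(fraction × n_node)` node
  pixels, making the realized fraction exact to within one pixel count —
  exactness of ground truth beats visual realism for testing. A
  contiguous `"blob"` mode (pixels nearest a random seed pixel) exists for
  plausibility; it has the same count accuracy.
- **Intensity noise.** Uniform integer jitter `mean ± spread`, clipped to
  0–255. No distributional claim about real tissue is intended; uniform
  jitter is the least structured choice that still exercises the
  intensity gates. Default 52 ± 7 AU places positive scenes in the
  45–60 AU range typical of fluorescent nodes on this scale, clearing all
  built-in floors.
- **Color construction.** Fluorescent pixels are built at high saturation
  (default 220) so hue is well defined, with the interpolated RGB channel
  nudged by ±1–3 units so the *integer* pixel reproduces the requested
  0–255 hue exactly after rounding. Tissue color (default RGB
  210,180,170, hue ≈ 11) and white background are both far outside the
  blue band.
- **Canvas.** 512 × 512 by default; the source imaging system's still
  dimensions are not publicly specified, and nothing downstream depends on
  canvas size. Tests use 128-px canvases for speed.

Perturbation modes emulate the failure modes described for real
photographs — `dull_fluorescence` (intensities pulled toward 32 AU, between
the 30 and 45 AU floors), `fat_occlusion` (a contiguous part of the signal
overwritten with tissue color, ground truth updated), and `ambient_light`
(a faint warm background tint, off-band by construction).

What passing on synthetic scenes does **not** show: robustness to JPEG
artifacts, specular reflections, node-boundary ambiguity, hand-drawn-ROI
variability, or any property of real ICG distribution. The generator
validates the *measurement arithmetic and its contracts*, not the imaging
physics.

### Median filtering and scattered-subset scenes

A median filter removes isolated pixels by design, and subset-mode scenes
*are* isolated pixels. Ground-truth-recovery checks therefore quantify
subset scenes with `filter_radius = 0`, while negative-control contracts
run the full chain including the radius-1 filter (on a negative control
the filter is provably harmless: each window holds at most two colors, and
the per-channel median of a two-color window is the majority color).
Photographic input should keep the default radius 1.

## Numerical choices

- **HSI conversion** computes the hexagonal hue angle directly from the
  integer channels (`60·((G−B)/Δ mod 6)` and cyclic variants) and rounds
  `angle × 255/360` to integer. `grDevices::rgb2hsv` pre-scales channels
  to [0,1], which can round the opposite way at exact .5 boundaries; since
  hue gates thresholds, the package owns the arithmetic and keeps
  `rgb2hsv` as a ±1 cross-check in the tests.
- **Median filter**: per-channel, square window, replicate (clamp-to-edge)
  padding so every window has an odd count and the output is a true order
  statistic of observed values. Implemented in C++ (Rcpp).
- **Circle/ellipse rasterization** is pixel-center containment. The
  background circle picks its radius from the sorted squared lattice
  distances so the realized area is as close as possible to the 5,806-px
  convention (lattice counts cannot hit arbitrary targets; the realized
  area is within ~0.15%).
- **Kappa** is computed from the contingency table with identity, linear
  (Cicchetti–Allison) or quadratic (Fleiss–Cohen) weights; the CI uses the
  large-sample Fleiss–Cohen–Everitt variance and the p-value the
  corresponding null variance. The study behind the workflow does not
  state its weight scheme; linear is the default, quadratic a flag.
  `kappa = 1` collapses the CI to a point; both-raters-constant tables are
  an error, not a silent `NaN`.
- **Empty signal masks** yield 0 AU by convention — the value a negative
  control must report — rather than `NaN`.
- **ROC cut-points** are midpoints between consecutive distinct intensity
  values (plus sentinels), predicted-positive at `fi ≥ c`; the optimum
  maximizes Youden's J with ties broken toward higher specificity, the
  more clinically useful side for an intensity test. AUC is trapezoidal
  and equals the Mann–Whitney `U/(n₁n₂)` identity, which the tests assert.
  Under complete separation the logistic slope diverges; the fit is
  flagged unconverged and Wald quantities are `NA`, while the empirical
  ROC and cut-point (which remain well defined) are still reported.
- **Friedman test** on fully tied rows (identical columns) is defined as
  statistic 0, p = 1; the underlying tie-corrected statistic is 0/0 there
  but carries no evidence against the null by construction.
- **Determinism**: every stochastic operation takes a seed and restores
  the caller's RNG state; identical spec ⇒ bit-identical scene, identical
  config+seed ⇒ byte-identical run artifacts.

## Problem sizes

The shipped tests run on 128-px canvases (≈3,500-px nodes), fraction grids
of 11 points × 3 seeds, rating tables of 20–80 pairs, and a synthetic
cohort of 83 nodes (48 positive / 35 negative, matching the near-balanced
design such validation studies aim for); the whole suite completes in
seconds. Oracle-equivalence checks run on ≤32×32 images and ≤20-pair
tables where brute force is exact and instant. These sizes are the
package's own choice: every contract checked is size-invariant, and the
512-px default canvas is exercised by the acceptance script and the worked
example.

## Known limitations

- Pseudo-color analysis cannot see below the display threshold and
  saturates at 255; raw-NIR quantification is out of scope by design.
- ROI definition is manual (masks, ellipses, polygons); automated node
  segmentation is deliberately not attempted.
- Agreement statistics cover two raters; multi-rater generalizations
  (Fleiss' kappa and friends) are not implemented.
- The logistic/ROC module assumes a single intensity predictor, as in the
  workflow it validates.
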