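---
title: "Quantifying engulfment phenotypes: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying engulfment phenotypes: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engulfquant)
```

## Scope

Macropinocytic and phagocytic cups are ring-shaped actin protrusions
that close around a target. Their regulators segregate spatially: some
proteins concentrate at the protrusive rim, others fill the cup
interior (the active-Ras/PIP3 patch), and the boundary between the two
domains is where shape control happens. `engulfquant` quantifies this
organization from 2D fluorescence images and derived tables:

1. **Fold-enrichment profiles** along the membrane from cup tip to tip,
   and the rim ("tip") enrichment statistic.
2. **Two-channel registration** of active-Ras/active-Rac linescans to
   the Ras patch edge, and the spatial offset between the two domains.
3. **Patch morphometry** on whole-cell perimeters (size, count,
   perimeter fraction), **macropinosome volumetry** from maximum spot
   diameters, and **Feret-diameter shape classification** of engulfed
   targets.
4. **Chemotaxis track statistics** (speed, chemotactic index).
5. **Linear GAP-activity rates** from %GDP time courses.

Every stage has a matching synthetic-data generator with a recorded
ground truth, so the whole pipeline is testable by parameter recovery
without any external data.

## Fold-enrichment profiles

A linescan is drawn along the membrane between the two protrusive tips,
through the cup interior. With `B` the local extracellular background
and `I_np` the mean membrane signal on a non-protrusive reference
stretch, each raw intensity `I` becomes

```
E = (I - B) / (I_np - B)
```

so `E = 1` means "as much probe as ordinary membrane". Profiles are
rescaled to a normalized arc coordinate on `[0, 1]`, linearly
interpolated onto a fixed 1000-point grid, and averaged pointwise
across cups. The **tip enrichment** is the mean of the first 10% of the
grid (100 points at defaults). Because a tip-to-tip path has no natural
orientation, `tip_enrichment()` by default averages the leading and
trailing segments so both tips contribute; `symmetrize = FALSE`
restores a single designated tip. The normalization is exactly
invariant under affine intensity transforms `I -> aI + b` (gain,
offset) provided background and reference are measured on the same
transformed image; the test suite asserts this to float tolerance.

Interpolation is linear and never extrapolates beyond the profile
endpoints; the first and last values are preserved exactly, and
resampling is idempotent on the fixed grid. Profiles shorter than 10
samples are rejected rather than padded.

### Extraction defaults and their rationale

Membrane intensity is sampled with bilinear interpolation along the
normal to the contour, averaging a band of `width` pixels (default 5)
at half-pixel steps. Half-pixel quadrature keeps the dependence of the
recovered membrane amplitude on the sub-pixel phase of the membrane
below ~0.5%; single-pixel sampling can vary by ~10% with phase and is
kept available (`width = 1`) for perimeter-wide patch profiling, where
cross-membrane averaging is not wanted.

The local background is the mean over a band 4-7 px outside the cell
adjacent to the cup. The synthetic membrane is rendered with a
1-px-sigma Gaussian cross-section; a band starting at 3 px sits at 3
sigma, where the membrane tail still biases fold-enrichment upward by
~0.08 at 3-fold enrichment, so the default starts at 4 px (~30-fold
less contamination). Both band radii are user-overridable.

At a cup tip the membrane folds back on itself, so samples within the
blur length of the corner mix the two membrane branches. The default
`trim_px = 3` removes the first and last 3 px of the path; the tip
statistic then reads the tip plateau rather than the corner artifact.

The reference region defaults to the contour's annotated non-protrusive
arc (the generator marks a 3 um arc diametrically opposite the cup);
coordinates are continuous micrometres with pixel centers at
half-integer pixel positions, origin top-left, y increasing downward.

## Edge-aligned two-channel profiles

Paired linescans run from the cup center outward past the rim. Each
channel is normalized by its own interior plateau, `I0` = mean of the
first 10 samples at native sampling (before any resampling), minus
background. The Ras patch edge is detected automatically as the
outermost position where the smoothed (0.3 um moving average),
background-subtracted signal falls through 50% of the interior plateau;
the outermost crossing is used because the patch edge abuts the
protrusion. Profiles are then shifted so the Ras edge sits at 0 um with
the interior negative. The manual-edge criterion used in practice by
microscopists is not standardized; the half-max rule is this package's
automated stand-in and both the threshold and the smoothing window are
configurable.

The **edge offset** statistic is the Rac-channel half-max crossing
minus the Ras-channel crossing, positive when Rac activity extends
beyond the Ras patch (the rim zone). The same symmetric smoothing is
applied to both channels first, which leaves the half-max of a clean
edge unchanged - identical channels report an offset of exactly 0, and
`edge_offset(A, B) = -edge_offset(B, A)`.

## Patch morphometry

`detect_patches()` thresholds perimeter-intensity samples at
`background mean + 2 sd` (configurable), finds contiguous runs with
full circular wrap-around, bridges gaps shorter than 0.5 um, and
discards patches shorter than 1 um. Boundaries are placed midway
between the last above- and first below-threshold samples; merging is
computed as circular connected components, so the result is invariant
to rotation of the arc-length origin (tested against a brute-force run
enumerator). Comparisons against the merge and minimum-arc constants
carry a 1e-9 guard so exact ties cannot flip with the origin.

Threshold crossing on a blurred step systematically overshoots the true
domain boundary by roughly the blur length on each side; on synthetic
cells with 0.1 um pixels this inflates patch sizes by ~0.3-0.5 um.
The paper-scale quantities (patch size, count, perimeter fraction
`phi = sum(sizes) / perimeter`, always in `[0, 1]`) inherit that bias;
it is reported here rather than corrected, since the same bias affects
any threshold-based reading of real images.

Macropinosome volumes use the spherical assumption
`V = (pi / 6) d^3` on measured maximum diameters, summarized per cell
and as cohort mean +/- SEM; cells with zero spots count 0 and are
excluded from the volume mean (flagged in the output).

Object shape uses caliper metrics on the convex hull of boundary-pixel
centers: the Feret diameter (maximum pairwise distance, the "long
axis") and the minimum caliper width via the rotating-calipers
identity. The center convention (not pixel corners) is fixed so the
implementation and its brute-force test oracle agree; it underestimates
true axes by up to ~1 px at sharp tips. Objects with caliper aspect
ratio at or above 1.5 are classed ellipsoid, otherwise spherical - a
boundary placed between the aspect ~1.0 (spheres) and ~2.6 (stretched
bead) populations; single-pixel objects are refused, not guessed.

## Track statistics

Speed is total path distance over elapsed time; the chemotactic index
is the net displacement projected on the (configured, never inferred)
gradient axis divided by total path length, signed, in `[-1, 1]` by the
triangle inequality. Irregular sampling is allowed: segments connect
consecutive available points with no interpolation, matching manual
tracking practice. Stationary tracks have speed 0 and an undefined
index (`NA`, flagged with a warning rather than an error).

## GAP kinetics

%GDP time courses are fit by ordinary least squares over windows that
start at the first time point, with lengths 4 to 8 points. The window
rule - the longest window with r-squared at or above 0.98, otherwise
the best-fitting window - makes the common "first 4-8 points" recipe
deterministic; all three constants are configurable, and the selection
is tested against an exhaustive `lm()` search. Flat series get rate 0
with r-squared defined as 0 (flagged). Relative GAP activity subtracts
the intrinsic (GAP-free) hydrolysis rate from both fits by default
(`subtract_intrinsic = FALSE` compares raw rates, since conventions
differ between labs), then reports control/test fold activity and the
percent reduction.

## The synthetic-data generator

The generators emulate, with explicit seeds and no global RNG state:

- **Cup images**: a circular cell (default radius 6 um, 0.1 um/px) with
  a circular-arc indentation spanning 30% of the perimeter; the tips
  are the indentation endpoints, which keeps all arc lengths analytic
  for test oracles. Membrane intensity along the contour is
  `B + (I_ref - B) E(s)` with a 1-px-sigma Gaussian cross-section;
  channel 2 is a uniform membrane marker. `E(s)` holds tip plateaus
  (first/last 10% of the cup arc) at the tip enrichment, a base plateau
  (central 30%) at the base enrichment, linear ramps between, and 1
  outside the cup. The plateaus are deliberate: a profile that peaks
  only at a geometric point would make the first-10%-mean statistic
  undershoot any target value, whereas real rim zones are extended
  regions. Noise is additive Gaussian clipped at 0 (Poisson shot noise
  behind `noise_model = "poisson"`).
- **Profile pairs**: falling logistic edges with configurable softness
  (0 = exact step), plateau/background per channel, a channel-B edge
  shifted by the true offset, and 0.1 um sampling to match the imaging
  pixel size.
- **Spot tables**: log-normal diameters (positive, right-skewed, as
  measured macropinosome diameters are; the exact family is a free
  choice) with Poisson spots per cell; the ground truth records the
  analytic mean sphere volume `(pi/6) exp(3 mu + 9 sigma^2 / 2)`.
- **Shape masks**: non-overlapping rasterized ellipses with per-object
  axes/orientation ground truth; rejection-sampled placement raises a
  packing error when a field is genuinely too crowded.
- **Tracks**: biased correlated random walks - each step heads up the
  gradient with probability equal to the directional bias, otherwise
  turns from the previous heading by a Gaussian angle (sd 0.6 rad);
  step lengths are Gaussian (truncated at 0) around `speed * dt`.
- **Kinetics**: `min(saturation, k t)` plus Gaussian noise, clipped to
  `[0, 100]`; default design is 10 points every 3 min, which keeps the
  4-8-point early window informative for rates between 1 and
  10 %GDP/min (at 1 %/min and 1% noise the least-squares slope error
  floor is ~4% of the rate; a shorter assay cannot resolve it to 5%).

What the generators do **not** emulate: cup closure dynamics, patch
splitting over time, 3D stacks, optics beyond the 1-px membrane blur,
spatially correlated noise, probe-affinity differences between
channels, or touching objects needing watershed separation. Passing
recovery tests therefore demonstrates correctness of the estimators
under the stated image-formation model, not robustness to every
property of real microscopy data.

## Numerical conventions

- All coordinates are micrometres; pixel centers at half-integers,
  origin top-left, y downward.
- Numeric CSV output uses a fixed `%.6f` format so repeated runs are
  byte-identical; every generator and every pipeline stage is
  deterministic given its inputs, configuration and seed.
- Sample standard deviations use the n-1 denominator; single-item
  cohorts report sd/SEM 0 and are flagged.
- Degenerate inputs (profiles under 10 samples, single-pixel objects,
  stationary tracks, flat kinetics) are rejected or flagged explicitly,
  never silently imputed.

## Problem sizes used in the tests

The recovery suites run noise-free tip/base recovery over a 4 x 3
enrichment grid, 20 noisy cups for the averaged-profile check, 20
replicates per edge-offset condition, 100 mixed beads, 50 kinetics
replicates per rate, and 1000-case invariance sweeps for the
chemotactic index and patch detection - sizes at which the Monte-Carlo
error of each check sits well below its acceptance margin.

## Worked example

```{r example, eval = FALSE}
# simulate a cup at 3-fold rim / 2-fold base enrichment and recover it
g <- generate_cup_image(cup_image_params(tip_enrichment = 3,
                                         base_enrichment = 2,
                                         noise_sd = 70, seed = 1))
profile <- extract_linescan(g$image, g$contour, pixel_size = 0.1)
ep <- resample_profile(fold_enrichment(profile))
tip_enrichment(ep)

# register a Ras/Rac pair and measure how far Rac extends past the edge
pp <- generate_profile_pair(profile_pair_params(channel_offset = 2,
                                                noise_sd = 50, seed = 1))
edge_offset(align_to_edge(pp$profile_A, pp$profile_B))
```
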