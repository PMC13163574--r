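---
title: "Methods: dynamic-subtraction flow indices and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic-subtraction flow indices and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cineflow)
```

## The model

`cineflow` treats a grayscale cine loop as a sampled scalar field and uses
temporal brightness change as a surrogate for blood displacement. No
velocity field is estimated: the method is deliberately scalar. For a
consecutive frame pair, the signed difference d = next − prev (range
−255…255) is mapped to an 8-bit differential grayscale

g = round((d + 255) / 2), halves rounded away from zero,

so g = 128 means no change, g → 0 maximal darkening and g → 255 maximal
brightening. The signed (not absolute) difference is kept so that the two
directions of change land on the two extremes of the gray axis; this makes
"black and white" the most movable blood and mid-gray the most stable.
The mapping is exactly invertible up to the 1-level rounding: the swap
identity g(A,B) + g(B,A) equals 255 for odd d and 256 for even d (both
half-values round away from zero), which the test suite checks by
exhaustive enumeration over all differences.

The differential is computed only inside the region of interest (ROI),
a closed polygon delineating the cardiac cavity. ROIs are keyframed:
polygons given on a subset of frames are resampled to a common vertex
count (default 64) by arc length, anchored at the first drawn vertex, and
interpolated vertex-wise and linearly in frame index between keyframes;
outside the keyframe range the nearest keyframe is held constant. Linear
vertex correspondence is this package's choice — manual delineation
workflows do not prescribe one. Each frame pair is masked with the ROI of
its *later* frame, and the differential frame is timestamped at the later
frame's acquisition time, so change is attributed to the moment it is
observed. Rasterisation uses pixel-centre (column − 0.5, row − 0.5)
even-odd containment, chosen because it is unambiguous and brute-force
verifiable against an independent containment oracle.

## Isophote bands and components

The differential grayscale [0, 256) is partitioned into five half-open
equal-width bands; 256 is not divisible by 5, so the remainder goes to
the top band (widths 51, 51, 51, 51, 52):

| layer | band        | role     | colour |
|------:|-------------|----------|--------|
| 1     | [0, 51)     | marginal | violet |
| 2     | [51, 102)   | medial   | blue   |
| 3     | [102, 153)  | median   | white  |
| 4     | [153, 204)  | medial   | orange |
| 5     | [204, 256)  | marginal | red    |

The median band holds the most stable blood; the default *active layers*
are therefore {1, 2, 4, 5}, configurable (all-layer processing is
supported, and the configuration is recorded in every export).

Within each band, connected components are labelled with 8-connectivity —
diagonal contact keeps visually contiguous speckle clusters together. A
component's perimeter is its unit-edge contour length: the number of pixel
edges adjacent to a pixel outside the component or outside the ROI, holes
included. This convention makes the perimeter an even integer ≥ 4,
computable as 4·area − 2·(4-adjacent same-component pairs), and gives the
turbulence index an exact discrete lower bound.

## The two indices

**Turbulence index.** TI = P / (2·√(π·A)) for a component of area A and
perimeter P — contour length relative to the circle of equal area. Under
the edge-count convention TI ≥ 2/√π ≈ 1.1284 for *every* pixel set, with
equality exactly for solid squares; the suite verifies this exhaustively
over all connected subsets of a 3×3 window and the underlying perimeter
bound P ≥ 4√A over all 65 535 subsets of a 4×4 window. Frame-level TI is
the area-weighted mean of component TIs (aggregate over active layers,
plus per-layer values). Area weighting is the default because large pools
dominate the flow field; an unweighted mean is available
(`weighted_ti = FALSE`) and the choice is recorded in exports.

**Blood mobility fraction.** BMF(c) = 100 · Σ A(retained) / A(ROI), where
retention keeps components of active layers with area ≥ c pixels. The
denominator is always the full ROI area, never the sum of layer areas.
BMF is non-increasing in the cutoff (a property tested frame-by-frame on
randomised phantoms) and the cutoff profile over c = 50…1200 characterises
flow fragmentation.

Frames in which no component survives filtering yield missing values, not
zeros, so cycle averages and max/min/range summaries are not biased
toward zero; missing values are excluded bin-wise and summary-wise.

## ECG gating and cycle averaging

R peaks are detected with the classical chain — band-pass (5–15 Hz
Butterworth, clamped below Nyquist for low sample rates),
differentiation, squaring, 150 ms moving-window integration, adaptive
threshold, 200 ms refractory window — and refined to the raw-trace local
maximum. The trace is reflect-padded by 0.5 s so edge beats are found. On
the package's stylised synthetic ECG the detector recovers truth peaks to
well under ±20 ms, the contract the tests assert.

Cycles are the first n complete R-R intervals; differential frames are
assigned by timestamp containment with a 10⁻⁹-relative tolerance so
frames falling exactly on a cycle boundary (index/frame-rate arithmetic)
are not lost to floating-point representation. Atrial phases are fixed
R-R fractions — reservoir [0, 0.4), conduit [0.4, 0.75), booster
[0.75, 1) by default, configurable and exported — because figure-level
phase marks do not define boundaries; when the R-R coefficient of
variation exceeds 0.15 (atrial fibrillation), cycles are still delimited
but phase labels are withheld, since aligning atrial mechanical phases to
an irregular ECG is not well defined. Cycle averaging resamples each
cycle's curve linearly onto 50 bins of normalised cycle time and reports
per-bin mean, sample SD (n − 1) and SE; a cycle with no frames is dropped
with a warning and at least two usable cycles are required.

## Cohort statistics

Per-patient summaries are max, min and range (max − min) of a BMF track
over non-missing frames. Group tables report the arithmetic mean and
sample SD (n − 1); display rounding is half-away-from-zero to one decimal
while exports keep full precision. Group comparison offers an exact
Mann–Whitney test — the full enumeration of all C(n₁+n₂, n₁) assignments
of the observed mid-ranked values, two-tailed p = P(|W − E W| ≥
|w(obs) − E W|) — which handles ties exactly, returns p = 1 for identical
groups, and matches `wilcox.test`'s exact p on tie-free data (a dual-route
check in the tests); a Welch t-test; and an `auto` mode that picks the
t-test only when both groups pass a Shapiro–Wilk screen at α = 0.05. The
method used is always recorded. Enumeration is used up to 10 patients per
group; beyond that the tie-corrected normal approximation takes over.

The bundled `bmf200_cohort()` dataset carries the published per-patient
BMF(200) summaries of a 16-patient ablation cohort as the worked example
for this stage. Its range column is kept exactly as reported, although in
two patients the reported range differs from max − min in the last
decimal — the dataset is a transcript, not a recomputation.

## What the phantom generator emulates — and what it does not

`phantom_spec()` / `make_phantom()` produce 8-bit speckle loops at 85
frames/s (the 80–90 fps acquisition regime) with periodic cardiac-cycle
kinetics (0.8 s cycles by default), a synchronised stylised P-QRS-T ECG
whose R peaks sit exactly at cycle starts, additive clipped Gaussian
sensor noise (SD 4 intensity units by default) and optional slow
"respiratory" modulation of motion amplitude. Regions are speckle
textures (smoothed white noise; the grain parameter is the smoothing
sigma in px, 0 = flat) moved by nearest-neighbour resampling with integer
displacements so 8-bit arithmetic stays exact and geometric oracles are
simple. Each region moves during a duty window at the start of the cycle
and rests otherwise, resetting at the next cycle start.

The `"active"` preset uses two flat bright pools (intensity 230 over
background 40) sweeping in opposite directions during the first 10 % of
each cycle: their leading and trailing edges form large coherent
marginal-band components, giving a high, phase-locked BMF(200) with a
wide max–min swing. The `"stale"` preset is the same-sized pool, static,
so only sensor noise separates frames and BMF(200) stays near zero. This
design was chosen over pure speckle-decorrelation motion because slicing
a decorrelation differential into five bands fragments it into components
that straddle the 200-px cutoff erratically — a property of band-sliced
noise, not of coherent flow. The two presets deliberately bracket the
order-of-magnitude contrast between active and stagnant flow.

The phantom's ground truth (`moved` masks) marks pixels of the
*noise-free* frames whose signed change leaves the median band (d ≥ 50 or
d ≤ −53 — the asymmetry comes from the rounding in the gray mapping). It
is computed directly from raw frames, independently of the analysis
pipeline, so BMF at cutoff 0 can be checked for exact equality in the
noise-free case.

What the phantom does **not** emulate: ultrasound physics (no point-spread
function, attenuation, reverberation or dropout), probe motion, gain
variation, real vortex hydrodynamics or blood viscosity. Passing phantom
tests therefore demonstrates that the pipeline measures what it defines —
not that the indices are clinically valid on real loops, which requires
recordings the package cannot synthesise.

## Numerical choices and problem sizes

- Gray mapping rounds halves away from zero; band boundaries are
  half-open; value 51 is blue, 204 is red, 128 is white.
- Degenerate inputs are contracts, not crashes: zero-area polygons
  rasterise to an empty mask with a warning; flat ECG traces return no
  peaks with a warning; an all-median frame yields missing TI and zero
  BMF; an empty mask yields an empty component set.
- DICOM fixtures round-trip intensities exactly; frame rate (decimal
  FrameTime) and ECG (16-bit quantisation with stored sensitivity)
  round-trip to ~1e-10 relative and ~3e-5 of the amplitude range
  respectively. The image-stack dialect round-trips everything exactly.
- Test and validation problem sizes are chosen for thoroughness per unit
  time: 96×96 px phantoms with 2–4 cycles (~140–270 frames) for
  end-to-end checks, 24–32 px noise fields for the 100-phantom
  monotonicity sweep, exhaustive enumeration confined to 3×3 (TI bound),
  4×4 (perimeter bound) and 256-level (gray mapping) spaces, and
  C(16, 8) = 12 870 assignments for the exact Mann–Whitney oracle.

## Known limitations

- Scalar differencing cannot distinguish direction of motion within a
  frame pair, and out-of-plane motion registers identically to in-plane
  motion.
- The five-band partition is fixed by design; no adaptive or
  histogram-equalised banding is offered.
- Atrial phase boundaries as fixed R-R fractions are a convention;
  mechanically-defined phases would need wall-motion input the method
  does not use.
- The DICOM codec covers little-endian multi-frame grayscale with the
  waveform sequence and common cine tags; compressed transfer syntaxes
  and vendor-private encodings are out of scope.
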