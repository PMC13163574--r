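# cineflow

Quantitative intracardiac blood-flow analysis from grayscale cine loops —
no contrast agent, no Doppler. `cineflow` is aimed at cardiac-imaging
researchers (electrophysiology, echo, MRI) who want dynamic, whole-chamber
flow surrogates from routine ECG-gated recordings: intracardiac echo (ICE)
loops at 80–90 frames/s, TEE/TTE, cine MRI or angiography.

## The method

As blood moves between two consecutive frames, pixel brightness changes.
`cineflow` builds **dynamically subtracted (differential) frames** inside a
user-delineated region of interest (ROI): for each pixel, the signed
difference *d* = next − prev ∈ [−255, 255] is mapped to grayscale
*g* = round((*d* + 255)/2), so mid-gray (128) marks stable blood and the
black/white extremes mark the most movable blood. The differential
grayscale is partitioned into **five equal-width isophote bands**
([0,51) violet and [204,256) red — marginal; [51,102) blue and [153,204)
orange — medial; [102,153) white — the stable median band), connected
components are labelled (8-connectivity) and filtered by a pixel-area
cutoff, and two indices are computed per frame:

- **Turbulence index (TI)** — for a component of pixel area *A* and
  unit-edge contour length *P*,

  TI = *P* / (2·√(π·*A*)),

  the ratio of the actual contour length to the perimeter of a circle of
  equal area; a boundary-fractality surrogate. Under the edge-count
  convention TI ≥ 2/√π ≈ 1.128, with equality exactly for solid squares.
  Frame-level TI is the area-weighted mean over retained components,
  aggregated and per layer.

- **Blood mobility fraction (BMF)** — the percentage of the ROI covered by
  retained components at a cutoff *c* (e.g. BMF(200) keeps components of at
  least 200 px):

  BMF(*c*) = 100 · Σ *A*<sub>retained</sub> / *A*<sub>ROI</sub>.

  Active, coherently moving blood produces large above-cutoff components
  and high BMF; stagnant, fragmented flow is cut away.

Index curves are gated on the ECG (classical band-pass/derivative/
integration R-peak detection), segmented into cardiac cycles with
reservoir / conduit / booster atrial phases at configurable R-R fractions,
averaged over cycles (mean, SD, SE per normalised-time bin), summarised
per patient (max / min / range of BMF) and compared between groups with an
exact enumeration Mann–Whitney test or a t-test.

The package also ships a multi-frame DICOM reader/writer (explicit and
implicit VR little endian, embedded ECG waveform) plus an image-stack
dialect, a speckle-phantom generator with exact ground truth for
validation, layer-coloured visualisation and full-precision digital export.

## Worked example

```r
library(cineflow)

# a synthetic "active flow" loop: 96x96 px, 85 fps, 3 cardiac cycles,
# with a synchronised ECG and known ground truth
ph <- make_phantom(phantom_spec("active", n_cycles = 3, seed = 1))

s <- index_series(ph$seq, cutoffs = c(50, 100, 200, 500))
glance(s)
#> # A tibble: 1 × 15
#>   n_frames duration ti_mean bmf_50_max bmf_50_min bmf_50_range bmf_100_max
#>      <int>    <dbl>   <dbl>      <dbl>      <dbl>        <dbl>       <dbl>
#> 1      203     2.38    1.48       34.7          0         34.7        34.7
```

203 differential frames over 2.38 s; BMF(50) swings from 0 % (quiescent
part of each cycle) to 34.7 % of the ROI while the pools sweep — an active,
phase-locked flow pattern. Gating on the R peaks and averaging:

```r
cyc <- segment_cycles(ph$truth$r_peaks, s, n_cycles = 3)
av  <- cycle_average(s, cyc, value = "bmf_200")
head(tidy(av), 3)
#> # A tibble: 3 × 6
#>     bin phase_time  mean    sd    se     n
#>   <int>      <dbl> <dbl> <dbl> <dbl> <dbl>
#> 1     1       0     27.8  12.0  6.94     3
#> 2     2       0.02  13.9   0    0        3
#> 3     3       0.04  13.9   0    0        3

autoplot(av)          # cycle-averaged BMF curve with SD/SE ribbons
```

Cohort statistics on the bundled worked-example dataset (16 ablation
patients, BMF(200) summaries; 8 paroxysmal vs 8 persistent AF):

```r
cmp <- compare_groups(bmf200_cohort(), "bmf_max", method = "mann_whitney")
tidy(cmp)
#> # A tibble: 1 × 5
#>   statistic_name estimate statistic p.value method
#>   <chr>             <dbl>     <dbl>   <dbl> <chr>
#> 1 bmf_max            15.8        54  0.0207 mann_whitney
```

The paroxysmal group's maximal BMF(200) is 15.8 percentage points higher
(31.1 % vs 15.3 % on average), significant at α = 0.05 by the exact
two-tailed Mann–Whitney test — the expected signature of more active,
phase-coupled atrial flow in sinus rhythm versus persistent AF.

A thin command-line front end covers the same workflow
(`inst/scripts/cineflow analyze | compare | synth`).

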