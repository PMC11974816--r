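---
title: "Methods: models, parameters and validation strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and validation strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamelloscope)
```

lamelloscope quantifies the signalling-to-motility axis of migrating
cells from five kinds of microscopy data: two-channel ratiometric
reporter movies, three-channel FRET biosensor movies, DIC/fluorescence
edge movies, platinum-replica electron micrographs, and nucleus
time-lapse movies (or exported detection tables). This vignette explains
the models behind each stage, the parameters that matter, the numerical
conventions, and what the synthetic-data validation does and does not
demonstrate.

## Conventions

Images are `(row, col)` matrices with 1-based indices and pixel centres
at integer coordinates; movies are `(time, channel, row, col)` arrays
(`channel_stack()`). All physical outputs are converted through the
stack's `pixel_size_um` and `frame_interval_s`. Intensities are promoted
to double precision on load; no saturation handling is applied. Along a
kymograph line the spatial axis runs from the cell interior to the
exterior, so outward (protrusive) edge motion is positive. In
cross-correlograms a positive lag means the signal leads the edge.

## Ratiometric mapping

The chain is: flat-field division by a cell-free blank (normalised to
unit mean, so intensity scale is preserved), rigid registration onto
frame 1, per-frame background subtraction, Gaussian denoising, division
of reporter by reference, and masking to the cell.

*Registration.* The default is translation estimated by phase
correlation with parabolic sub-pixel refinement, which is exact for
stage drift and testable against planted shifts; a dense mode estimates
per-tile translations and interpolates a smooth displacement field for
slowly varying non-rigid drift. Planted rigid drifts are recovered to
better than 0.2 px/frame.

*Background.* The background region is found by Otsu's threshold
(computed on the reference channel by default — the threshold channel is
a parameter, since the choice is not canonical) and each channel
subtracts the median of its own pixels in that region, per frame,
because illumination drifts over 10–20 min movies. In the calibration
context (below) the background region additionally excludes a 7-px
dilation of the cell mask: dim cell-edge pixels below the Otsu threshold
otherwise inflate the FRET-channel background median and bias the fitted
slope by about −1.5%.

*Ratio.* Both channels are smoothed with a σ = 0.5 px Gaussian before
division. Pixels outside the cell mask, or where the reference falls
below an adaptive guard (10⁻⁶ × the in-mask median reference), are
flagged `NA` rather than zero — zero is a legal ratio. The edge band
used by `edge_body_ratio()` is defined by the Euclidean distance
transform of the mask; the band threshold carries a 10⁻⁹ relative
tolerance so that physical depths that are exact pixel counts (e.g.
2.4 µm at 0.4 µm/px = 6 px) do not lose their outermost ring to floating
point.

With denoising disabled the full chain is an exact inverse of the
generator on noise-free input (pixelwise to < 10⁻⁹); with σ = 0.5 the
smoothing perturbs values only where the true map has curvature, which
is why the exactness check is run with `denoise_sigma = 0` and the noisy
check (SNR 20) asserts the edge/body summary within 5%.

## FRET bleed-through correction

Per pixel, on background-subtracted, registered channels:

$$E = \frac{F_\mathrm{raw} - \alpha\,D - \beta\,A}{D}$$

where $D$ and $A$ are the donor and acceptor intensities and $\alpha,
\beta$ the spectral bleed-through fractions. The calibration fit pools
in-mask pixels across frames of a single-fluorophore stack, discards
intensities outside the 1st–99th percentile (hot-pixel guard), and takes
the zero-intercept least-squares slope. A zero intercept is correct
because channels are background-subtracted first; the subtraction is
done *without* clipping negatives, since clipping zero-mean noise would
bias the slope upward. Negative fitted slopes are clamped to zero with a
warning. Calibration is a persisted artifact (`fret_calibration()`),
never a hard-coded constant.

Noise-free correction inverts the generator exactly (< 10⁻⁶ over a grid
of α ∈ [0, 0.5], β ∈ [0, 0.2], E ∈ [0, 0.8]), and the correction is
invariant to a common gain on all three channels. At SNR 20 the
estimator's residual bias is attenuation from noise in the regressor,
kept below 2% of α by the wide intensity profile of the calibration
cells.

## Edge dynamics

Kymographs sample intensity by bilinear interpolation along a line,
averaged over `width_px = 3` parallel offsets. The edge per frame is the
*outermost* crossing of the per-kymograph Otsu threshold (tracking the
membrane front past ruffles), refined by linear interpolation between
the bracketing samples; frames without a crossing are interpolated from
neighbours and flagged, and tracing aborts if more than half the frames
lack a crossing.

Velocity is a centred finite difference. Phase classification uses a
stall threshold of ±0.5 µm/min and merges runs shorter than 3 frames
into the longer neighbour; both values are exposed because no numeric
convention exists for them. The *fast spreading phase* is
operationalised as the contiguous window (≥ 20% of the trace)
maximising mean outward velocity, and the spreading speed is the
regression slope of position on time in that window — a reproducible
stand-in for reading the steep kymograph segment by eye. Protrusion
speed averages the regression slopes of the `n_events = 5`
largest-displacement protrusion runs; rank-by-displacement is our
selection rule, as "five protrusion events" does not define one.
Regression slopes may differ slightly and systematically from slopes
measured manually on screen.

## Edge–signal coupling

Both series are Gaussian-filtered (σ = 1 frame), mean-subtracted and
variance-scaled with the biased (1/n) denominator so coefficients are
bounded by 1 and the autocorrelation at lag 0 is exactly 1. Lags run to
⌊n/3⌋ frames to avoid unstable tails. The correlogram can be
spline-smoothed, with the peak relocated on a 10×-refined lag grid;
`smoothing_factor = 0` gives an interpolating spline. The default series
is edge *displacement* (with a velocity switch recorded in the output),
but note that a signal generated as a lagged copy of *velocity* — as the
edge-movie generator does — only yields a peak at the planted lag when
correlated against velocity. Smoothing is applied per cell; averaging
across cells happens afterwards.

## Meshwork porosity

Preprocessing is Gaussian blur then a white top-hat with a 15-px-radius
disc (image minus its opening), which removes slowly varying background
and keeps features thinner than the structuring element. EBImage's
grayscale morphology operates on the [0, 1] range, so the image is
unit-scaled in and out of the transform. The default blur is
σ = 0.5 px: with ~3 px filaments a σ = 1 blur measurably widens the
segmented filaments and biases porosity low by about 0.05, while 0.5
suppresses pixel noise with a residual bias near 0.01.

Binarisation is two-cluster Lloyd k-means on the pixel intensities with
deterministic initialisation at the 25th/75th percentiles
(bit-reproducible masks; no random restarts); the brighter cluster is
foreground. Porosity is the background fraction of the ROI. Pore sizes
are connected components of the inverted mask (4-connected by default,
8-connected optional); components touching the ROI border are excluded
from size statistics (their area is censored) but still count toward
porosity, and components below `min_area_px = 5` are discarded — this
size cut stands in for particle-filtering steps whose settings are not
enumerable, and is reported with every result. The pipeline expects
filament-bright images; inverted-contrast micrographs are flipped with
`invert = TRUE`.

## Morphometrics

Projection is a per-pixel maximum over z followed by the Otsu-median
background subtraction. ROI means use the even-odd rule on pixel
centres. Control normalisation divides every measurement by the mean of
the control measurements, fixing the control mean at exactly 1. The
enriched-perimeter fraction thresholds at the whole-cell mean +
`k_sd = 1.5` SD; the boundary is traced as an ordered Moore-neighbour
chain and each boundary point is scored on the mean marker intensity in
its in-mask disc of radius `band_px = 5` — the band depth is our
formalisation of an otherwise visual "edge enrichment" call, and `k_sd`
is a strict parameter where the original call was approximate.
Focal-adhesion bins are half-open by explicit convention — nascent
[0.05, 0.20), mature [0.20, 1.75], fibrillar (1.75, ∞) — because prose
ranges overlap at their edges; areas below 0.05 µm² are dropped and
counted.

## Tracking

The LoG detector responds at scale σ = diameter/(2√2) with per-image
response normalisation, so the 0.08 quality threshold transfers across
intensity scales. Linking minimises total squared displacement per frame
pair by optimal assignment over an augmented cost matrix whose non-link
alternative costs `max_link_um²`; gap closing joins segment ends to
later segment starts (frame difference 2..`max_frame_gap`) the same way.
The assignment problem is solved exactly by a shortest-augmenting-path
Hungarian solver implemented in the package and verified against
brute-force enumeration. Track filters require ≥ 60 min duration and
≥ 18 µm span; span is interpreted as *path length* ("spanned" applied to
the whole trajectory), with net displacement available as a switch.
Metrics: speed = path/duration; DI = displacement/path (0 when the path
is 0); 3-D displacement speed = net displacement/duration in µm/hr.
Division-truncated or 3-D tracks are accepted as pre-made tables in
TrackMate-compatible CSV.

## The synthetic-data generator

Each generator returns its inputs plus the planted truth, and is
deterministic given a seed. Design choices:

- **Cell shape** is a disc with a half-elliptical protruding lobe,
  giving a well-defined free-edge normal for kymograph lines.
- **Ratio maps** place the peak ratio in a fixed-depth edge band (a step
  profile), so the generator's edge/body contrast is exactly the
  peak/body parameter ratio and survives read-back through the same
  distance-transform band.
- **Shading** is a smooth multiplicative bump normalised to unit mean,
  so flat-field division restores intensities exactly.
- **Noise** is additive Gaussian with configurable SD — camera noise is
  not otherwise specified, and a Gaussian keeps recovery tolerances
  analytic. A constant camera floor (default 100 for calibration stacks)
  keeps negative-going noise from clipping at zero.
- **Single-fluorophore stacks** carry no energy transfer (a donor-only
  cell has no acceptor), so their FRET channel is exactly
  coefficient × fluorophore + noise.
- **Meshworks** are long anti-aliased chords crossing the field (random
  anchor, angle, and near-diagonal length). Short segments with uniform
  endpoints clump into solid blobs wider than the top-hat structuring
  element at low porosity — geometry no filament-extraction step can
  preserve and unlike a branched actin network, whose long filaments
  intersect into polygonal pores.
- **Edge movies** advance a straight edge by a per-phase velocity plan;
  the pixel straddling the edge carries a coverage-weighted intensity
  (as a finite-resolution detector would record), which is what makes
  sub-pixel tracing accurate to 0.5 px. The near-edge signal band sits
  behind a 1-px rim of constant intensity so the edge step has
  time-invariant contrast. An optional smooth velocity wobble gives the
  velocity series enough structure for a well-defined correlation peak.
- **Tracks** are constant-step correlated random walks (turn ∝ 1 −
  persistence): persistence 1 gives straight lines with step speed
  exactly the speed parameter; dropout removes interior detections to
  exercise gap closing.

What passing these tests shows — and does not. Recovery of planted
parameters demonstrates that each stage inverts its own forward model
under controlled noise. The generators do not simulate a microscope
PSF, photobleaching, shot noise, ruffle texture, nuclear shape change,
or cell–cell contact; agreement on synthetic data therefore validates
the arithmetic and the estimators, not performance on any particular
real dataset.

## Problem sizes and runtime

The validation suite uses 128×128 to 192×192 images, movies of 60–100
frames, 20-frame calibration stacks, and 10–20 seeds per stochastic
check; these sizes give stable recovery statistics while keeping the
full suite near twenty seconds on one core. The same generators scale to
larger fields if heavier validation is wanted.

## Known limitations

Registration assumes mostly rigid drift; the dense-flow mode handles
slow non-rigid drift but not large deformation. Edge tracing assumes one
dominant foreground-to-background transition per kymograph column.
k-means binarisation assumes a bimodal intensity distribution after
top-hat filtering and will mis-split images whose filament and
background modes overlap heavily. The LAP linker does not model
division (splitting) or merging; tracks across division events should be
truncated upstream. The 1.5-SD perimeter enrichment rule is sensitive to
intracellular intensity heterogeneity inherited from its definition.
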