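# lamelloscope

Quantitative image analysis of lamellipodial dynamics: from calcium and
RhoA-biosensor movies to actin ultrastructure and single-cell migration.

## What it is for

Migrating fibroblasts steer their leading edge through a signalling axis
that couples mechanosensitive Ca²⁺ influx, CaMKII, RhoA activity and
branched-actin assembly. Quantifying that axis from microscopy requires a
chain of bespoke measurements that are usually scattered across ImageJ
plugins and one-off scripts:

- **Ratiometric reporter maps** (e.g. GCaMP6f/mCherry): shading
  correction with a cell-free blank, drift registration, Otsu-median
  background subtraction, Gaussian denoising (σ = 0.5 px), reporter ÷
  reference, and masking to the cell; summarised as an edge-to-body
  ratio.
- **FRET bleed-through correction** for GTPase biosensors:

  `E = (FRET_raw − α·donor − β·acceptor) / donor`

  with α (donor → FRET) and β (acceptor → FRET) calibrated from
  single-fluorophore cells by zero-intercept regression of FRET on
  fluorophore intensity.
- **Kymograph edge dynamics**: 3-px-wide line kymographs, sub-pixel edge
  tracing, spreading speed (slope of the fast-spreading phase),
  protrusion speed (mean slope of the five largest protrusion events),
  and protrusion/stall/retraction phase classification.
- **Edge–signal coupling**: normalised cross-correlation of edge
  displacement (or velocity) with the mean of the 4 px of reporter signal
  closest to the edge, both Gaussian-filtered (σ = 1 frame), with
  spline-smoothed lag estimation. Positive lag means the signal leads the
  edge.
- **Actin meshwork porosity** from platinum-replica EM: Gaussian blur,
  white top-hat, two-cluster k-means binarisation; porosity is the
  background fraction, pore sizes are the void components of the inverted
  mask.
- **Morphometrics**: maximum-intensity projection + background
  subtraction, polygon-ROI means normalised to a control group,
  marker-enriched perimeter fraction (threshold = whole-cell mean +
  1.5 SD), and focal-adhesion classification by area
  (nascent [0.05, 0.20) µm², mature [0.20, 1.75] µm², fibrillar
  > 1.75 µm²).
- **Nucleus tracking**: LoG detection (25 µm diameter, quality ≥ 0.08),
  optimal-assignment frame-to-frame linking (50 µm radius) with gap
  closing (50 µm, ≤ 3 frames), track filters (≥ 60 min, ≥ 18 µm), then
  speed = path/duration and directionality index DI =
  displacement/path.

Every stage is validated against a bundled synthetic-data generator with
known ground truth (planted ratios, bleed-through coefficients,
porosities, edge trajectories, lags, and walker tracks), so the whole
pipeline is testable without any microscopy data.

## Worked example

Calibrate donor bleed-through from a synthetic donor-only stack, measure
meshwork porosity, and compute migration metrics:

```r
library(lamelloscope)

# donor-only calibration stack at SNR 20, generated with alpha = 0.3072
sim <- simulate_fret_triplet(n_frames = 5, acceptor_present = FALSE,
                             noise_sd = 50, seed = 1, background_level = 100)
estimate_bleedthrough(sim$stack, "donor")
#> FretCalibration: alpha = 0.30548, beta = NA

# EM-like meshwork with a planted void fraction
mesh <- simulate_meshwork(n_filaments = 70, seed = 1)
meshwork_analysis(mesh$image)
#> MeshworkResult: porosity 0.380, 209 pores, mean pore 45.6 px^2
round(mesh$truth$true_porosity, 3)
#> [1] 0.387

# correlated random walkers -> tracks -> metrics
trk <- simulate_tracks(n_cells = 4, n_frames = 20, speed_um_min = 1,
                       persistence = 0.7, seed = 2)
tracks <- link_tracks(trk$detections)
track_metrics(tracks, frame_interval_s = 720)[, c("track_id", "speed_um_min", "di")]
#>   track_id speed_um_min         di
#> 1        1            1 0.84195726
#> 2        2            1 0.73779584
#> 3        3            1 0.56514870
#> 4        4            1 0.04976854
```

The recovered α sits within 1% of the generating value, the measured
porosity within 0.01 of the planted fraction, and each walker's step
speed is recovered exactly; DI falls with decreasing persistence, as it
should.

`run_pipeline()` chains all stages on seeded synthetic data and writes
stage CSVs plus a JSON manifest (config snapshot, seeds, output hashes)
that makes a run bit-reproducible.

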