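---
title: "Quantifying spatiotemporal biosensor activity in migrating cells"
author: "fretPolarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatiotemporal biosensor activity in migrating cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretPolarity)
```

## The measurement problem

Raichu-type FRET biosensors report the activity of a Rho-family GTPase
(here, Rac) as the ratio of acceptor (YFP) to donor (CFP) emission:
GTP loading increases FRET, so the pixel-wise ratio image
$R(x, t) = I_{\mathrm{acceptor}}(x, t) / I_{\mathrm{donor}}(x, t)$
maps where and when the GTPase is switched on. Under TIRF illumination
only the basal ~100-200 nm of the cell is excited, giving a single-plane
movie of activity at the substrate-attached surface of, for example, a
neutrophil adhering, polarising, migrating or engulfing a particle.

Turning such two-channel movies into numbers requires a chain of steps,
each of which this package implements and tests:

1. **Channel registration.** The two emission channels are collected on
   separate cameras behind a beam splitter, so they are misaligned by a
   small planar transform. Multispectral beads imaged in both channels
   provide landmarks; `estimateRegistration()` fits the affine map from
   acceptor to donor coordinates by least squares (with iterative
   re-matching so that misalignments of several pixels do not seed wrong
   landmark pairs), and `applyRegistration()` resamples the acceptor
   stack bilinearly, flagging out-of-frame samples invalid.
2. **Ratio imaging.** `smoothMovie()` applies a circular mean filter of
   radius 2 px (13-pixel support), and `computeRatio()` divides the
   channels wherever the donor clears an intensity floor, producing a
   `RatioMovie` whose defined pixels are finite and positive by
   construction. `pseudocolor()` renders it through a discrete 16-level
   blue-to-red lookup table.
3. **Segmentation and tracking.** `segmentFrame()` (Otsu threshold,
   hole filling, optional watershed) yields per-frame masks with area,
   perimeter and circularity $4\pi A/P^2$; `buildTrack()` derives
   sub-pixel contours, centroids, a smoothed unit heading, and the
   leading-edge/uropod anchors as the contour points extremal along the
   heading.
4. **Polarity readouts.** `axisProfile()` samples the ratio along the
   leading-edge-to-uropod chord and reduces it to twenty 5% bins;
   `kymograph()`, `edgeBandValues()` (0.4 um peripheral band),
   `polarMap()` (eccentric-circle plots aligned to the chemoattractant
   needle) and `peakTrace()` (pole-zone dwell, switch events, wave
   durations) quantify where activity sits and how it moves.
5. **Motility and phagocytosis.** `frontPixelVelocity()`,
   `classifyPhases()`, `classifyMigrating()`, `detectProtrusions()`,
   `turningLatency()` and `movementPlot()` classify and measure
   migration; `detectParticles()`, `phagosomeTrace()` and
   `countUptake()` quantify engulfment.

## The synthetic-movie generator

No public reference movies exist for this kind of assay, so the package
ships a first-class simulator (`renderMovie()`, `renderBeadField()`,
`renderPhagocytosisScene()` and the `scene*()` presets) that emulates
every scenario the analysis quantifies, with full ground truth
(`GroundTruth`: true ratio images, masks, pole positions, peak
trajectory, phase labels, event times).

The model is deliberately phenomenological, not mechanistic:

* **Shape.** A star-shaped contour: a harmonically perturbed ellipse in
  the heading frame (default body 15.6 um x 9 um -- twice the 7.8 um
  half body length of a polarized neutrophil -- with harmonic
  amplitudes 0.06 and 0.03), plus optional protrusion bumps whose
  amplitude grows linearly from a programmed onset.
* **Activity field.** Strictly positive ratio field: baseline (1.2) +
  front-high longitudinal gradient + travelling Gaussian peak whose
  axial position follows a pole-to-pole triangle wave (a full cycle of
  16 s therefore contains two 8 s waves) + optional multiplicative
  enrichment in a peripheral band.
* **Rendering.** Donor = uniform cell brightness; acceptor = true ratio
  x donor signal, evaluated analytically in the (optionally misaligned)
  acceptor camera frame -- so with noise off the ratio round trip is
  exact to numerical precision, which the tests exploit.
* **Noise.** Poisson photon noise then additive Gaussian read noise per
  channel, the standard EM-CCD approximation. "SNR 10" test conditions
  use ~100 expected photons per cell pixel.

What the simulator does **not** emulate: reaction-diffusion dynamics of
the GTPase, donor bleed-through (an optional coefficient exists in the
rendering convention but defaults to 0), photobleaching, uneven
illumination, focus drift, and cell-cell contacts. Passing recovery
tests therefore demonstrate that the *analysis* is correct and
well-calibrated, not that it is robust to every real-world artifact.

## Parameters that matter

| parameter | default | unit | meaning |
|---|---|---|---|
| `pixel_size_um` | 0.27 | um/px | nominal for a 60x objective on a 16 um camera pixel; always configurable |
| `frame_interval_s` | 1 or 5 | s | assay-dependent sampling |
| `smooth_radius_px` | 2 | px | circular mean-filter radius before the ratio |
| `min_area_um2` | 40 | um^2 | adhesion count excludes objects *smaller than* this (boundary retained) |
| `auc_window_s` | 125 | s | AUC window for spreading/activity time courses |
| `phase_min_duration_s` / `phase_displacement_um` | 20 / 2 | s / um | migrating vs stalling phases: centre-of-mass displacement per window |
| `migrating_half_body_um` | 7.8 | um | net displacement over 2 min classifying a chemotaxing cell as migrating (inclusive) |
| `pole_zone_um` | 0.8 | um | axial distance from an anchor counting as leading-edge/uropod zone |
| `edge_band_um` | 0.4 | um | peripheral band for edge sampling |
| `axis_bins` | 20 | -- | 5% bins along the cell axis; bins 2-3 summarize the leading edge, 18-19 the uropod |
| `particle_diameter_um` | 2 | um | phagocytosis target size |

## Design choices and numerical conventions

* **Affine registration.** The physical misalignment of a two-camera
  splitter is translation + small rotation (+ scale), which an affine
  map captures exactly and invertibly; elastic registration is
  deliberately out of scope. Synthetic camera rotations pivot on the
  image centre. Accuracy: <= 0.1 px RMS noiseless, <= 0.3 px at SNR 10.
* **"Mean filter of two pixels"** is read as a *radius*: the discrete
  disk $dx^2 + dy^2 \le 4$ with 13-pixel support. At image borders the
  mean runs over the in-frame part of the disk, so constants are
  preserved exactly. A 2x2-kernel reading was considered and rejected
  as it has no well-defined centre.
* **Division guard.** The ratio is defined only where the donor clears
  a floor (background + 3 read-noise SDs when metadata is present,
  else 1% of the donor dynamic range). Guarding avoids the bias an
  added epsilon would introduce into low-signal ratios.
* **Perimeter.** Length of the corner-cut (moving-average, window 5)
  boundary-pixel-centre polygon plus the half-pixel Minkowski offset
  $\pi$; near-exact on rasterized disks and rectangles, keeping
  circularity within [0, 1.05] (the 0.05 allowance absorbs residual
  rasterization bias).
* **Axis and bins.** The longitudinal axis is the chord from the
  leading-edge anchor to the uropod anchor (not a medial-axis
  skeleton); samples are midpoints at <= 0.5 px spacing, averaged over
  a 3-px band normal to the axis, with the sample count a multiple of
  the bin count so the mean of the bin means equals the profile mean
  exactly.
* **Peak tie-breaks.** The per-frame peak is the argmax of the
  *un-binned* profile; exact ties resolve toward the previous frame's
  peak, then toward the leading edge, preventing spurious pole switches
  on flat profiles. No switch is inferred across a frame gap.
* **Oscillation counting.** A "wave" is the interval between successive
  pole-switch events, so a full pole-to-pole-and-back cycle contains
  two waves; the convention is recorded in the `PeakTrace` object.
  Whether a published oscillation count means switches or full cycles
  is ambiguous; switches are counted here.
* **Pole zones** are measured along the axis from each anchor,
  inclusive at the boundary (distance <= 0.8 um belongs to the zone).
* **Stationary-cell heading.** With no displacement the heading falls
  back to the mask's principal axis, with its sign chosen toward the
  pole of greater extent from the centroid (the protrusive front of a
  polarized outline) and then held by continuity. Anchor extraction
  takes, among contour points within half a pixel of the extreme
  projection, the one nearest the central axis -- flat rasterized tips
  otherwise bias the anchor sideways.
* **Phase segmentation** thresholds the per-step centre-of-mass speed
  at (displacement / duration) after a rolling *median* (window 3),
  which suppresses single-frame jitter without eroding run boundaries
  the way a rolling mean would; runs shorter than the minimum duration
  stay unlabeled. The companion textual definition of phases by
  leading-lamella activity is treated as interpretation; the
  displacement criterion is the operational classifier.
* **Front-pixel velocity** uses the leading-edge anchor (deterministic,
  intensity-noise-robust) over non-overlapping 20 s windows, with the
  anchor trajectory lightly smoothed (5 s rolling mean) to remove the
  upward bias pixel jitter adds to slow speeds.
* **Protrusion detection** measures contour advance against the mask
  several frames back (lag sized so a threshold-rate protrusion moves
  ~2 px) and back-extrapolates the onset with the event's steady rate;
  defaults (0.05 um/s advance, 2 um arc, 5 s sustain) are calibrated
  on synthetic scenes because the original assay was scored by eye.
  The simulated turning scene grows its bump at 0.25 um/s so that the
  sub-pixel onset quantization (~0.5 px / growth rate) stays below one
  frame interval.
* **"One cell diameter"** (random-migration criterion) is the
  equivalent-circle diameter of the cell's mean mask area.
* **Engulfment.** Contact = particle boundary within one pixel of the
  cell mask; fully engulfed = particle disk inside the mask eroded by
  one pixel (erosion guards against boundary flicker); the phagosomal
  readout is the in-mask annulus (0.5 um) around the particle, where
  the cup membrane and hence the sensor signal lives. The simulator
  programs the particle path so these predicates flip decisively at
  the stated frames, with margins exceeding mask rasterization.
* **Frames are 1-based** with frame $f$ at time $(f-1)\,\Delta t$;
  positions are micrometre coordinates with pixel $(r, c)$ centred at
  $((c-0.5)\,s, (r-0.5)\,s)$ and angles measured by `atan2` in image
  coordinates (y down), so due west is 180 deg and screen-north is
  270 deg.

## Problem sizes used in validation

Validation scenes are 96-160 px square, 2-120 frames at 1 s (2 min
chemotaxis-style runs) or 40 frames at 5 s (phagocytosis), one cell per
scene -- small enough that the whole suite runs in about a minute while
still exercising every code path at realistic cell-to-image scale. The
noise-variance check pools 500 frames of a constant scene; registration
recovery repeats over several random affines per run.

## Known limitations

* Segmentation assumes one dominant cell per field; touching cells are
  split by watershed only on request, and the tracker follows the
  largest object.
* Protrusion detection cannot distinguish protrusion from whole-cell
  translation; it is meant for stationary/polarising cells.
* Edge-band angular bins about the centroid can be empty for strongly
  concave outlines at fine angular resolution; empty bins are NA and
  are averaged away when maps are combined across cells or frames.
* Absolute areas and thresholds from manually drawn masks in the
  original assay are not recoverable; only relative and boundary
  behavior is validated.
* Group summaries stop at mean/SD/SEM/n by design; inferential
  statistics are left to standard tools.
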