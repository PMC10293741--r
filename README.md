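# fretPolarity

Quantification of spatiotemporal Rho-GTPase activity from two-channel
ratiometric FRET biosensor movies of living cells.

## The problem

Raichu-type biosensors report GTPase activity (e.g. Rac in migrating
neutrophils) through Förster resonance energy transfer: GTP loading
brings donor and acceptor fluorophores together, so the pixel-wise
emission ratio

&nbsp;&nbsp;&nbsp;&nbsp;*R*(x, t) = *I*<sub>acceptor</sub>(x, t) / *I*<sub>donor</sub>(x, t)

maps activity across the basal cell surface in TIRF time-lapse movies.
Getting from two raw camera channels to biology — where activity sits
between leading edge and uropod, how its peak oscillates pole-to-pole,
how fast the cell moves and when it stalls, how activity surrounds a
forming phagosome — takes a long chain of image-analysis steps, each
with conventions that matter. `fretPolarity` implements that chain as
tested, reusable R functions (Bioconductor-style S4 classes over
EBImage), for cell biologists and imaging analysts who want the same
readouts reproducibly:

* bead-based affine **channel registration** (`estimateRegistration`,
  `applyRegistration`),
* **ratio movies** with validity masking (`smoothMovie`,
  `computeRatio`, `pseudocolor` with a 16-level LUT),
* **segmentation and shape** (`segmentFrame`: area, perimeter,
  circularity 4πA/P²; `countAdherent` with the < 40 µm² exclusion),
* **tracking** (`buildTrack`: contours, heading, leading-edge/uropod
  anchors),
* **polarity profiling** (`axisProfile` 20-bin line scans,
  `kymograph`, `edgeBandValues` 0.4 µm peripheral band, `polarMap`
  eccentric-circle plots, `peakTrace` pole dwell / switch / wave
  statistics with 0.8 µm pole zones, `frontBackSummary` AUC of bins
  2–3 vs 18–19),
* **motility** (`frontPixelVelocity` over 20 s windows,
  `classifyPhases` by ≥ 20 s / 2 µm centre-of-mass displacement,
  `classifyMigrating` with the inclusive 7.8 µm half-body-length rule,
  `detectProtrusions`, `turningLatency`, `movementPlot`),
* **phagocytosis** (`detectParticles`, `phagosomeTrace` with contact /
  full-engulfment timing, `countUptake`),
* a **pipeline and config layer** (`runPipeline`, `defaultRunConfig`,
  `summarizeGroups` for mean ± SEM tables) and a thin CLI at
  `inst/cli/fretpolarity.R`,
* and a first-class **synthetic-movie generator** with ground truth
  (`renderMovie`, `renderBeadField`, `renderPhagocytosisScene`,
  `scene*()` presets) that stands in for live-cell data in every test.

See the vignette (`vignettes/quantifying-biosensor-polarity.Rmd`) for
the model, conventions and design decisions.

## Worked example

Simulate a 2-minute chemotaxis-style movie (1 s frames) whose peak
activity oscillates pole-to-pole with a 16 s full cycle, register a
misaligned bead pair, and run the pipeline:

```r
library(fretPolarity)

beads <- sceneBeads(10, misalignment = affineTransform(dx = 1.5 * 0.27,
                                                       dy = -0.5 * 0.27),
                    noise = FALSE, seed = 1L)
estimateRegistration(beads$movie)
#> RegistrationModel (acceptor -> donor affine)
#>      [,1] [,2]   [,3]
#> [1,]    1    0 -0.405
#> [2,]    0    1  0.135
#> residual: 7.169e-06 px over 8 landmarks

sc  <- sceneOscillation(cycle = 16, frames = 120L, noise = TRUE, seed = 1L)
computeRatio(smoothMovie(sc$movie))
#> RatioMovie: 128 x 128 px, 120 frames, 11.3% pixels defined

res <- runPipeline(sc$movie, defaultRunConfig(), writeOutputs = FALSE)
res$polarity$peakTrace
#> PeakTrace: 120 frames, 14 switches, mean wave 8.00 s, dwell front/rear 8.0/7.0 s
```

Reading the output: the recovered transform is the inverse of the
injected (+1.5, −0.5) px camera shift (−0.405/0.27 = −1.5 px) with a
negligible landmark residual; about 11% of pixels carry a defined ratio
(the cell's footprint); and the peak-activity trace finds 14
pole-switch events in 120 s with a mean wave duration of 8.0 s — two
waves per 16 s pole-to-pole-and-back cycle, as constructed.

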