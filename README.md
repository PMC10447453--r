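# fibrescope

Image reconstruction for multicore fiber-bundle (coherent imaging fiber)
endomicroscopy, aimed at label-free multimodal imaging with CARS, SHG and
TPEF contrast.

A coherent imaging fiber carries an image as ~10,000 individual light-guiding
cores arranged on a quasi-hexagonal lattice (mean core-to-core centre
distance ~4.69 µm inside a ~460 µm imaging circle). Raw frames recorded
through such a probe show two artifacts: a honeycomb pixelation from the core
lattice, and strong per-core brightness differences from variable core
transmission. `fibrescope` implements the full correction workflow plus the
sampling calculus and a forward simulator with ground truth, for anyone
building or evaluating this class of endoscopic probes:

1. **Stack alignment** — phase cross-correlation with subpixel refinement
   corrects the slow incoupling drift (about one core distance per 100
   frames) so the core lattice occupies the same pixels in every frame.
2. **Downscaling** — flux-preserving area-average rescale to
   2 × 2.3 = 4.6 px per core distance (Nyquist for the lattice, doubled for
   packing irregularity).
3. **Median projection** — the per-pixel temporal median estimates each
   core's transmission efficiency without any external reference; a running
   median over the last 100 frames gives automatic recalibration.
4. **Normalization** — per-pixel division by the median projection, with a
   floor mask so dead cores and inter-core gaps cannot blow up.
5. **Stitching** — linear-blend mosaicking of the normalized tiles at their
   stage positions, with the probe magnification (1.17, sample site /
   incoupling site) applied to tile placement.
6. **FFT bandpass** — an annular spectral filter removes the residual core
   structure from the mosaic.

Alongside the pipeline it provides the optical sampling calculus
(single-shot Nyquist pitch `2.3 × d`, effective spot size
`sqrt(psf² + core²)`, inscribed field of view `D/√2`, frame timing),
multi-frame **shifted superposition** (averaging sub-core-shifted frames on
an upsampled grid to fill the space between cores), and evaluation metrics
(line profiles, modulation depth, phase-folded stripe contrast, smallest
resolved pitch, peak SNR, NRMSE/SSIM fidelity, RGB compositing with the
fixed coding red = CARS, blue = SHG, green = TPEF).

Because no raw probe data are publicly deposited, the package ships a
first-class forward simulator: jittered hexagonal bundles with per-core
diameters (2.2–3.7 µm) and log-normal transmissions, bead / stripe / tissue
phantoms, per-core sampling through the effective excitation spot,
channel-dependent excitation exponents, incoupling drift, and Poisson + read
noise. Every simulated quantity retains its ground truth for testing.

## Worked example

```r
library(fibrescope)

## a default FIGH-type bundle and a flat calibration scene
map <- generateBundle(BundleSpec(), seed = 1)
nCores(map)                        # 8726
nearestNeighborStats(map)$mean     # 4.61 (µm)

## simulate a drifting 25-tile flat-field series and reconstruct it
scene <- makeFlatScene(1, c(400, 400), 1)
meta  <- AcquisitionMeta(stagePositions = stageGrid(5, 5, 25),
                         nx = 192, ny = 192, pixelScale = 0.55,
                         driftPerTile = c(4.69 / 100, 0), seed = 1)
stack <- acquireSeries(scene, map, meta)
res   <- runPipeline(stack, PipelineConfig(), intermediates = TRUE)

## the per-core gains recovered by the median projection correlate r > 0.99
## with the simulator's true t^p, and the mosaic is flat: ~3% RMS including
## the field edges, ~1.7% over the interior
img <- mosaicImage(res$mosaic)
sd(img, na.rm = TRUE) / mean(img, na.rm = TRUE)   # 0.031
```

The command-line entry point (`inst/scripts/fibrescope`) exposes the same
functionality; its `info` subcommand prints the sampling calculus:

```
$ fibrescope info
single-shot Nyquist pitch : 10.6 um
effective spot size       : 3.3 um
inscribed square FOV      : 325 um
frame time (256x256 px)    : 0.524 s
```

10.6 µm is the smallest single-shot-resolvable pitch implied by the 4.6 µm
core spacing (factor 2.3), 3.3 µm the effective excitation spot (1.6 µm PSF
combined with the 2.9 µm mean core in quadrature), 325 µm the side of the
square inscribed in the 460 µm imaging circle, and 0.52 s the 256 × 256 px
frame time at 2 µs dwell with 4 averages.

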