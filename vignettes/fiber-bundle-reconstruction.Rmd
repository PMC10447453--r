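---
title: "Depixelating multicore fiber-bundle endomicroscopy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depixelating multicore fiber-bundle endomicroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fibrescope)
```

# The imaging problem

A coherent imaging fiber transfers an image as roughly ten thousand
individual cores packed on a quasi-hexagonal lattice. At the proximal end a
laser-scanning microscope rasters the fiber facet; at the distal end a
miniature optical assembly relays each core's light into the tissue, where
nonlinear signals (CARS, SHG, TPEF) are generated and collected through a
separate multimode fiber. Every raw frame is therefore the tissue signal
*sampled at the core positions*, painted over the core apertures, and
modulated by each core's transmission. Two artifacts dominate:

* a **honeycomb pixelation** at the core lattice period (mean core-to-core
  centre distance 4.69 µm, imaging circle ~460 µm, core diameters
  2.2–3.7 µm);
* **fixed-pattern gain**: per-core transmission varies strongly, and the
  laser incoupling drifts slowly (about one core distance per 100 frames),
  so the gain pattern moves within a long acquisition.

`fibrescope` implements the correction workflow, the optical sampling
calculus, a forward simulator with ground truth, and the evaluation metrics
used to quantify all of it.

# The correction workflow

The pipeline applies six stages in a fixed order; `runPipeline()` exposes
per-stage intermediates for audit.

**1. Alignment.** Offsets of every tile against the first tile (options:
previous, running mean) are estimated by spectral cross-correlation —
the normalized cross-power spectrum's peak, refined to subpixel precision by
evaluating the inverse DFT on a locally upsampled grid (default 1/20 px).
Tiles are resampled bilinearly; a correlation peak below a threshold leaves
the tile unshifted and flagged. Alignment runs at raw resolution, before
downscaling, because the subsequent division is extremely sensitive to
lattice misregistration.

**2. Downscaling.** Raw frames are heavily oversampled (2048² px in
practice). Processing needs only `samplingPxPerSpacing = 2 × 2.3 = 4.6`
pixels per core distance: 2.3 is the Nyquist factor appropriate to a
quasi-hexagonal lattice, and the factor 2 absorbs core-diameter variation
and packing irregularity. The rescale uses **area averaging** implemented on
an integral image, which preserves the mean (flux) exactly up to masked-edge
effects — important because these values are about to be divided. The core
spacing on the raw grid is estimated from the first tile's radially averaged
magnitude spectrum: the lattice's six-fold Bragg ring radius gives the
lattice *row* spacing, `sqrt(3)/2` times the centre distance, and the
estimator applies that hexagonal factor.

**3. Median projection.** The per-pixel temporal median of the aligned,
downscaled stack estimates each core's local efficiency: tissue moves
between tiles while the core pattern is static, so the median keeps the
pattern and rejects the scene. No external reference is needed, the map can
come from a different measurement, and `updateRunningMedian()` maintains a
bounded window (default 100 frames) for automatic recalibration under slow
drift. The map is clamped at zero (read noise can push dark-pixel medians
slightly negative).

**4. Normalization.** Every pixel of every tile is divided by the map.
Pixels whose map value falls below `efficiencyFloor` (default 5%) of the
map's median are floored in the division and masked invalid (NA): dead cores
and inter-core gaps carry no signal and must not explode. The floor value is
a design choice the source procedure leaves open; 5% keeps ~99% of
core-covered pixels while rejecting the genuinely dark ones.

**5. Stitching.** Normalized tiles are placed at their stage positions, with
tile coordinates scaled by the probe magnification (1.17, sample site /
incoupling site — applied to placement and pixel scale, never to pixel
values). Overlaps use linear blending: each tile's weight is its distance to
the nearest tile edge, weights are accumulated and normalized so effective
weights sum to one wherever covered, and invalid pixels get zero weight.
Stitching constant tiles is exact (a regression-tested invariant).

**6. FFT bandpass.** An annular spectral filter passes spatial periods
between `bandpassSmallCutUm` (default 1.5 × the sample-plane core spacing,
≈8.2 µm) and `bandpassLargeCutUm` (default the tile extent), removing any
remaining lattice structure. Edges are raised cosines of 20% relative width
**centred on each cut-off** (half power at the cut-off, the standard filter
convention). The DC bin is kept by default, so the global mean is preserved
exactly; the filter is linear.

## Shifted superposition

Recording many frames with lateral shifts smaller than the core spacing
(e.g. a 10 × 10 grid of 1 µm steps) samples the space between cores.
`superimposeShifted()` places normalized frames on a common upsampled grid
at their shift offsets and averages valid contributions per pixel, cropping
to the rectangle covered by every frame. Resolution is then limited by the
effective spot and the core aperture rather than the lattice. The benefit
over a *bandpassed* single shot is twofold: genuine sub-lattice structure is
reconstructed, and aliased "wavy" artifacts average out.

# The optical sampling calculus

* `nyquistResolution(d, 2.3)`: smallest single-shot-resolvable pitch,
  2.3 × core distance — 2.3 × 4.6 ≈ 10.6 µm. This is a conservative
  sampling-theorem figure for generic two-dimensional structure (see
  "Resolution law" below for how grating measurements relate to it).
* `spotSize(psf, core)`: the effective excitation spot. Two rules are
  implemented because the available description is ambiguous: quadrature
  `sqrt(psf² + core²)` reproduces the quoted 3.3 µm exactly from the 1.6 µm
  facet-plane PSF and 2.9 µm mean core; a literal Gaussian ⊛ disk
  convolution of the 1.9 µm object-plane PSF gives ≈2.8 µm FWHM instead.
  Quadrature is the default; the convolution rule is computed numerically
  (1-D chord-integral reduction, verified against a brute-force 2-D
  convolution in the tests).
* `inscribedFov(D)`: the largest inscribed square, `D/√2` → 325 µm at
  460 µm.
* `frameTime(nx, ny, dwell, averages)`: unidirectional scan without
  flyback; 256 × 256 px at 2 µs and 4 averages gives 0.52 s. Measured times
  on real scan hardware include flyback and are longer (32 s measured vs
  33.6 s computed at 2048²).

# The forward simulator

The simulator stands in for undeposited probe data; everything it draws is
seeded and keeps its ground truth.

**Bundle geometry.** Cores sit on an ideal hexagonal lattice at the
specified spacing, perturbed by a *spatially correlated* displacement field
(Gaussian field, correlation length ≈2 spacings) whose per-core RMS equals a
uniform draw from a disk of radius `latticeJitterFrac × spacing`. Correlated
disorder is what drawn fiber actually shows — neighbouring cores deform
together — and it preserves the *measured* mean nearest-neighbour distance
at the nominal spacing (4.61 µm at the defaults). Independent per-core
jitter of the same amplitude would shrink the nearest-neighbour mean by ~9%
(minimum-over-neighbours statistics), contradicting the convention that the
spacing parameter *is* the measured average. Diameters are uniform in
[2.2, 3.7] µm; transmissions are log-normal with mean 1 and CV 0.2 (positive
support; the real distribution is unreported); 1% of cores are dead.

**Acquisition.** For core *i*, the scene (blurred by a Gaussian of the
effective spot FWHM, default 3.3 µm) is sampled at the magnification-scaled
core position plus the stage offset; the recorded value is `t_i^p · s_i`
with excitation exponent `p` = 3 for CARS (two pump photons and one Stokes
photon traverse the same core) and 2 for SHG/TPEF — the true mapping in a
real probe is unknown, so `p` is configurable and the reconstruction is
exponent-agnostic (the median projection simply estimates `t^p` as a whole).
The tile raster paints each core's value over its aperture (uniform disk
with one-pixel antialiased edge; Gaussian optional) on a dark inter-core
background. Incoupling drift translates the *core lattice in raster
coordinates* (the scan pattern drifting over the facet) while the recorded
content stays fixed — this is the drift that stack alignment observes and
corrects; drift accumulates linearly by default (random-walk option), with
the default rate calibrated to one core distance per 100 tiles. Noise is
Poisson at a configurable photons-per-unit-signal scale plus Gaussian read
noise, averaged over the configured frame count. Channel defaults (CARS:
250 photons/unit, read σ 0.025; SHG/TPEF: 60, 0.06) put single-frame peak
SNR in the tens, the regime reported for probes of this class; the exact
published SNR definition is not reproducible from the available text, so
`peakSnr()` is a documented surrogate ((smoothed peak − background mean) /
background sd) and no numeric equality is asserted.

**Phantoms.** Bead fields (antialiased disks, unit signal on a low
non-resonant background, rejection-sampled placement or explicit centres),
binary stripe gratings (pitch, duty, orientation), smoothed random
tissue-like fields with a channel mixing matrix for partial co-localization,
and flat scenes for calibration.

What the simulator deliberately omits: inter-core mode coupling, coherent
speckle, polarization, depth sectioning, scan-timing artifacts and
wavelength-dependent guidance. Passing tests therefore demonstrate the
correctness of the *reconstruction machinery* under the stated forward
model, not robustness to every artifact of real probe data.

# Metrics and the resolution law

`lineProfile()` averages an ROI perpendicular to its long axis;
`modulationDepth()` scores peak/valley/peak triplets as
`(mean peaks − valley)/(mean peaks + valley)`. For stripe sweeps the package
adds `stripeContrast()`: the profile is folded modulo the known pitch and
the folded period's modulation is measured. Folding is essential below the
sampling limit — aliased wavy patterns have the wrong frequency and cancel,
while true stripe transfer survives — otherwise spurious peak/valley pairs
from aliasing and noise masquerade as modulation.
`smallestResolvedPitch()` interpolates the pitch at which contrast crosses a
threshold (default 0.1, a Rayleigh-like criterion made explicit because a
single number is otherwise ill-defined for inhomogeneous lattice sampling).

Running the sweep (`resolutionSweep()`, 4–20 µm, three seeds, bundle and
noise at defaults) the single-shot pipeline's measured crossing sits at
≈8.0 µm, *better* than the 10.6 µm sampling-theorem figure. Two effects
explain this, and both are properties of the measurement rather than bugs:
a hexagonal lattice's half-row interleave samples any fixed grating
direction at ≈ spacing/2 in projection, so gratings (the most favourable
possible target) genuinely transfer below the generic two-dimensional limit;
and the default bandpass already blocks periods below ≈8 µm, which pins the
crossing to its edge. The 10 × 10 × 1 µm shifted superposition moves the
crossing to ≈5.9 µm, strictly better, limited now by the 3.3 µm spot and the
core aperture. Bead pairs behave as the theory predicts: touching 8 µm pairs
show a clear valley in a normalized single shot (mean modulation ≈0.3)
while 3 µm pairs do not (≈0.03).

# Numerical choices and degenerate inputs

* Coordinates: bundle-centred µm, x right / y down; raster origin top-left,
  pixel centres at half-integers. One stated convention avoids off-by-half
  errors across the simulator, stitcher and metrics.
* Interpolation: area averaging for downscaling (flux-preserving), bilinear
  for subpixel shifts and resampling; NA marks invalid pixels everywhere and
  propagates conservatively (50% coverage rule in the area resize).
* Overlapping cores (possible at extreme jitter) rasterize nearest-centre
  wins, with a warning.
* Division by zero is structurally impossible: the efficiency floor masks
  weak map pixels before the division.
* All lengths in metadata are µm; pixel units exist only inside rasters.
  TIFF output stores 32-bit samples scaled to [0, 1] with the affine
  intensity scale recorded in the JSON metadata (quantization ≈2⁻³²
  relative), because that is what the available TIFF writer supports;
  round-trips are verified to 10⁻⁶ relative.
* Every stochastic operation derives its stream from (seed, tile index), so
  single tiles are reproducible in isolation and whole runs are
  byte-identical under a fixed seed; manifests record config, seeds and
  stage parameters, and `NA` (run-time-derived) cut-offs serialize as
  `"auto"` to round-trip losslessly.

# Problem sizes

The shipped tests and the acceptance script run the full default bundle
(460 µm, ~8.7k cores) with a central 106 µm scan field of 192² px at
0.55 µm/px — the same reduced-central-field strategy used on the real probe
to avoid damaged edge cores — with 21–25-tile calibration stacks, 100-tile
drift and superposition series, and three-seed resolution sweeps. These
sizes exercise every code path at full geometric fidelity while keeping a
complete run in minutes on one CPU; all of them scale up by changing
`AcquisitionMeta`/`PipelineConfig` fields only.

# Known limitations

* The simulator's clean forward model makes resolution measurements
  slightly optimistic relative to real probes (no inter-core coupling, no
  scan-timing artifacts, perfectly known magnification).
* The peak-SNR metric is a surrogate; absolute SNR values depend on its
  definition and on ROI placement over the structured core pattern.
* Alignment assumes pure translation; rotation or scale drift of the
  incoupling is not modelled or corrected.
* Online (real-time) stitching and positional tracking are out of scope.
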