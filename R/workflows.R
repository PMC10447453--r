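## Higher-level workflow helpers for simulation studies: calibrate a
## flat-field map once, then reconstruct single shots or shifted-superposition
## sets of arbitrary scenes through the same bundle.

#' Build a flat-field calibration from a flat-scene tile series
#'
#' Acquires `nTiles` frames of a uniform scene through the bundle, estimates
#' the core spacing from the first raw frame, downscales to the target
#' sampling and computes the median-projection efficiency map. The map can
#' then normalize any later acquisition through the same bundle (the
#' flat-field reference need not come from the measurement it corrects).
#'
#' @param map a [CoreMap-class]
#' @param cfg a [PipelineConfig-class]
#' @param nTiles calibration frames (>= 21 recommended)
#' @param nx,pixelScaleUm raster geometry of the scan field
#' @param windowUm flat-scene window (um); must cover the magnified field
#' @param seed integer seed
#' @param channel acquisition channel
#' @return list with `efficiency` ([EfficiencyMap-class]), `spacingPx` (raw
#'   grid), `meta` (the calibration [AcquisitionMeta-class])
#' @export
calibrateFlatField <- function(map, cfg = PipelineConfig(), nTiles = 21L,
                               nx = 192L, pixelScaleUm = 0.55,
                               windowUm = c(300, 300), seed = 1L,
                               channel = "CARS") {
  grid <- stageGrid(ceiling(nTiles / 3), 3, 15)[seq_len(nTiles), , drop = FALSE]
  meta <- AcquisitionMeta(stagePositions = grid, channel = channel,
                          nx = nx, ny = nx, pixelScale = pixelScaleUm,
                          seed = seed)
  st <- acquireSeries(makeFlatScene(1, windowUm, 1), map, meta)
  spacingPx <- estimateCoreSpacing(tiles(st)[[1]], pixelScaleUm)$spacing_px
  ds <- downscaleStack(st, spacingPx, cfg)
  list(efficiency = medianProjection(ds), spacingPx = spacingPx, meta = meta)
}

#' Reconstruct a single shot of a scene through the bundle
#'
#' Acquires one frame, downscales with the calibration's spacing, divides by
#' the calibration efficiency map and (optionally) applies the annular FFT
#' bandpass — the single-shot arm of the resolution analysis.
#'
#' @param scene a [Scene-class]
#' @param map a [CoreMap-class]
#' @param calibration result of [calibrateFlatField()]
#' @param cfg a [PipelineConfig-class]
#' @param seed integer seed for the acquisition noise
#' @param bandpass apply the FFT bandpass after normalization
#' @param channel acquisition channel
#' @return list with `image` (matrix, sample-plane), `pixelScale` (um/px)
#' @export
reconstructSingleShot <- function(scene, map, calibration,
                                  cfg = PipelineConfig(), seed = 1L,
                                  bandpass = TRUE, channel = "CARS") {
  cal <- calibration
  meta <- AcquisitionMeta(stagePositions = matrix(0, 1, 2), channel = channel,
                          nx = cal$meta@nx, ny = cal$meta@ny,
                          pixelScale = cal$meta@pixelScale, seed = seed)
  tile <- acquireTile(scene, map, meta, 1L)
  st <- new("TileStack", tiles = list(tile), meta = meta, coreMap = map,
            driftTrace = matrix(0, 1, 2))
  ds <- downscaleStack(st, cal$spacingPx, cfg)
  nrm <- normalizeStack(ds, cal$efficiency, cfg)
  img <- tiles(nrm)[[1]]
  scl <- pixelScale(nrm) * cfg@magnification
  if (bandpass) {
    spacingSampleUm <- cal$spacingPx * cal$meta@pixelScale * cfg@magnification
    smallCut <- if (is.na(cfg@bandpassSmallCutUm))
      1.5 * spacingSampleUm else cfg@bandpassSmallCutUm
    largeCut <- if (is.na(cfg@bandpassLargeCutUm))
      max(dim(img)) * scl else cfg@bandpassLargeCutUm
    img <- fftBandpass(img, scl, smallCut, largeCut, keepDC = cfg@keepDC)
  }
  list(image = img, pixelScale = scl)
}

#' Reconstruct a scene from sub-core-shifted frames
#'
#' Acquires one frame per shift, normalizes each by the calibration map and
#' superimposes them on an upsampled common grid — the multi-frame
#' resolution-enhancement arm (e.g. 10 x 10 frames at 1 um steps).
#'
#' @inheritParams reconstructSingleShot
#' @param shiftsUm n x 2 matrix of stage shifts (um), e.g.
#'   `stageGrid(10, 10, 1)`
#' @param upsample output-grid upsampling factor
#' @return list with `image`, `pixelScale`
#' @export
reconstructSuperposed <- function(scene, map, calibration,
                                  shiftsUm = stageGrid(10, 10, 1),
                                  cfg = PipelineConfig(), seed = 1L,
                                  upsample = 3L, channel = "CARS") {
  cal <- calibration
  meta <- AcquisitionMeta(stagePositions = shiftsUm, channel = channel,
                          nx = cal$meta@nx, ny = cal$meta@ny,
                          pixelScale = cal$meta@pixelScale, seed = seed)
  st <- acquireSeries(scene, map, meta)
  ds <- downscaleStack(st, cal$spacingPx, cfg)
  nrm <- normalizeStack(ds, cal$efficiency, cfg)
  mos <- superimposeShifted(tiles(nrm), shiftsUm, upsample = upsample,
                            pixelScaleUm = pixelScale(nrm),
                            magnification = cfg@magnification)
  list(image = mosaicImage(mos), pixelScale = pixelScale(mos))
}

#' Stripe-phantom resolution sweep
#'
#' Measures the phase-folded stripe contrast of reconstructions over a series
#' of grating pitches, in single-shot or shifted-superposition mode, averaged
#' over seeds (each seed draws its own bundle and noise).
#'
#' @param pitchesUm grating pitches (um, sample plane)
#' @param seeds integer seeds
#' @param mode "single" or "superposed"
#' @param cfg a [PipelineConfig-class]
#' @param windowUm scene window (um)
#' @param shiftsUm shift grid for the superposed mode
#' @param spec a [BundleSpec-class]
#' @return data.frame with `pitch_um` and `contrast` (seed average)
#' @export
resolutionSweep <- function(pitchesUm, seeds = 1:3,
                            mode = c("single", "superposed"),
                            cfg = PipelineConfig(), windowUm = c(300, 300),
                            shiftsUm = stageGrid(10, 10, 1),
                            spec = BundleSpec()) {
  mode <- match.arg(mode)
  acc <- matrix(0, length(pitchesUm), length(seeds))
  for (k in seq_along(seeds)) {
    sd <- seeds[k]
    map <- generateBundle(spec, sd)
    cal <- calibrateFlatField(map, cfg, windowUm = windowUm, seed = sd)
    for (i in seq_along(pitchesUm)) {
      scene <- makeStripePhantom(pitchesUm[i], 0, 0.5, windowUm)
      rec <- if (mode == "single") {
        reconstructSingleShot(scene, map, cal, cfg, seed = sd + 500L)
      } else {
        reconstructSuperposed(scene, map, cal, shiftsUm, cfg,
                              seed = sd + 900L)
      }
      acc[i, k] <- stripeContrast(rec$image, pitchesUm[i], rec$pixelScale)
    }
  }
  data.frame(pitch_um = pitchesUm, contrast = rowMeans(acc))
}
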