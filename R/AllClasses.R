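#' @import methods
NULL

## Central S4 classes. Conventions used throughout the package:
##  * lengths are micrometres (um) in all metadata; pixels only inside rasters;
##  * coordinates are bundle-centred, x to the right, y downwards;
##  * rasters are numeric matrices indexed [row = y, col = x], origin top-left,
##    pixel centres at half-integer positions: pixel (i, j) has its centre at
##    (origin + (j - 1) * pixelScale, origin + (i - 1) * pixelScale) where
##    `origin` is the coordinate of the centre of pixel (1, 1);
##  * invalid pixels are NA inside tile/mosaic matrices.

#' Fiber-bundle geometry specification
#'
#' Describes the multicore imaging fiber as a jittered hexagonal lattice of
#' light-guiding cores inside a circular imaging area. Defaults describe a
#' FIGH-10-500N-type bundle: a ~460 um imaging circle holding on the order of
#' 10,000 cores at a mean core-to-core centre distance of 4.69 um, with
#' individual core diameters between 2.2 and 3.7 um.
#'
#' @slot imagingDiameter diameter of the circular imaging area (um)
#' @slot meanCoreDistance mean core-to-core centre distance (um)
#' @slot coreDiameterMin,coreDiameterMax bounds of the core diameters (um)
#' @slot latticeJitterFrac per-core positional jitter radius as a fraction of
#'   the lattice spacing, in [0, 0.5)
#' @slot transmissionCV coefficient of variation of the per-core transmission
#' @slot deadCoreFrac fraction of non-guiding (dead) cores, in [0, 1)
#' @exportClass BundleSpec
setClass("BundleSpec",
  slots = c(
    imagingDiameter   = "numeric",
    meanCoreDistance  = "numeric",
    coreDiameterMin   = "numeric",
    coreDiameterMax   = "numeric",
    latticeJitterFrac = "numeric",
    transmissionCV    = "numeric",
    deadCoreFrac      = "numeric"
  )
)

setValidity("BundleSpec", function(object) {
  len <- c(imagingDiameter = object@imagingDiameter,
           meanCoreDistance = object@meanCoreDistance,
           coreDiameterMin = object@coreDiameterMin,
           coreDiameterMax = object@coreDiameterMax)
  if (any(!is.finite(len)) || any(len <= 0))
    return(sprintf("all lengths must be positive; got %s",
                   paste(names(len)[!is.finite(len) | len <= 0], collapse = ", ")))
  if (object@coreDiameterMin > object@coreDiameterMax)
    return("coreDiameterMin must be <= coreDiameterMax")
  if (object@coreDiameterMax >= object@meanCoreDistance)
    return("coreDiameterMax must be < meanCoreDistance (cores must not touch)")
  if (object@latticeJitterFrac < 0 || object@latticeJitterFrac >= 0.5)
    return("latticeJitterFrac must lie in [0, 0.5)")
  if (object@transmissionCV < 0)
    return("transmissionCV must be >= 0")
  if (object@deadCoreFrac < 0 || object@deadCoreFrac >= 1)
    return("deadCoreFrac must lie in [0, 1)")
  TRUE
})

#' @param imagingDiameter,meanCoreDistance,coreDiameterMin,coreDiameterMax,latticeJitterFrac,transmissionCV,deadCoreFrac
#'   see the corresponding slots.
#' @rdname BundleSpec-class
#' @export
BundleSpec <- function(imagingDiameter = 460, meanCoreDistance = 4.69,
                       coreDiameterMin = 2.2, coreDiameterMax = 3.7,
                       latticeJitterFrac = 0.1, transmissionCV = 0.2,
                       deadCoreFrac = 0.01) {
  new("BundleSpec",
      imagingDiameter = imagingDiameter, meanCoreDistance = meanCoreDistance,
      coreDiameterMin = coreDiameterMin, coreDiameterMax = coreDiameterMax,
      latticeJitterFrac = latticeJitterFrac, transmissionCV = transmissionCV,
      deadCoreFrac = deadCoreFrac)
}

#' Realized fiber-bundle core map
#'
#' A concrete draw from a [BundleSpec-class]: core centre positions (um,
#' bundle-centred), per-core diameters and per-core transmission gains
#' (dead cores have transmission 0).
#'
#' @slot centers n x 2 matrix of core centres (x, y) in um
#' @slot diameters per-core diameter (um)
#' @slot transmissions per-core dimensionless gain, >= 0
#' @slot spec the generating [BundleSpec-class]
#' @slot seed integer seed used by [generateBundle()]
#' @exportClass CoreMap
setClass("CoreMap",
  slots = c(
    centers       = "matrix",
    diameters     = "numeric",
    transmissions = "numeric",
    spec          = "BundleSpec",
    seed          = "integer"
  )
)

setValidity("CoreMap", function(object) {
  n <- nrow(object@centers)
  if (ncol(object@centers) != 2L)
    return("centers must be an n x 2 matrix")
  if (length(object@diameters) != n || length(object@transmissions) != n)
    return("centers, diameters and transmissions must have equal length")
  if (n > 0) {
    r <- sqrt(rowSums(object@centers^2))
    if (any(r > object@spec@imagingDiameter / 2 + 1e-9))
      return("all core centres must lie within the imaging circle")
    if (any(object@transmissions < 0))
      return("transmissions must be >= 0")
  }
  TRUE
})

#' Optical parameters of the probe head
#'
#' Holds the quantities entering the sampling/resolution calculus: the
#' simulated excitation PSF full width at half maximum at the fiber facet
#' (image plane) and at the object plane, the mean core diameter, the Nyquist
#' oversampling factor used for quasi-hexagonal lattices, and the
#' probe magnification (sample site / incoupling site).
#'
#' @slot psfFwhmImage PSF FWHM at the fiber facet (um)
#' @slot psfFwhmObject PSF FWHM at the object plane (um)
#' @slot meanCoreDiameter mean core diameter (um)
#' @slot nyquistFactor sampling factor applied to the core spacing (>= 2)
#' @slot magnification sample-plane / facet-plane magnification
#' @exportClass OpticsSpec
setClass("OpticsSpec",
  slots = c(
    psfFwhmImage     = "numeric",
    psfFwhmObject    = "numeric",
    meanCoreDiameter = "numeric",
    nyquistFactor    = "numeric",
    magnification    = "numeric"
  )
)

setValidity("OpticsSpec", function(object) {
  v <- c(object@psfFwhmImage, object@psfFwhmObject, object@meanCoreDiameter,
         object@nyquistFactor, object@magnification)
  if (any(!is.finite(v)) || any(v <= 0)) return("all parameters must be positive")
  if (object@nyquistFactor < 2) return("nyquistFactor must be >= 2")
  TRUE
})

#' @param psfFwhmImage,psfFwhmObject,meanCoreDiameter,nyquistFactor,magnification
#'   see the corresponding slots.
#' @rdname OpticsSpec-class
#' @export
OpticsSpec <- function(psfFwhmImage = 1.6, psfFwhmObject = 1.9,
                       meanCoreDiameter = 2.9, nyquistFactor = 2.3,
                       magnification = 1.17) {
  new("OpticsSpec", psfFwhmImage = psfFwhmImage, psfFwhmObject = psfFwhmObject,
      meanCoreDiameter = meanCoreDiameter, nyquistFactor = nyquistFactor,
      magnification = magnification)
}

#' Sample-plane scene
#'
#' Ground-truth signal density per imaging channel over a rectangular
#' sample-plane window. All channels share the grid; values are non-negative
#' signal densities in arbitrary units.
#'
#' @slot channels named list of numeric matrices (CARS, SHG, TPEF)
#' @slot pixelScale um per scene pixel
#' @slot origin coordinate (x, y) of the centre of pixel (1, 1), um
#' @slot provenance one of "bead", "stripe", "tissue", "flat"
#' @slot params generating parameters (list), for provenance/audit
#' @exportClass Scene
setClass("Scene",
  slots = c(
    channels   = "list",
    pixelScale = "numeric",
    origin     = "numeric",
    provenance = "character",
    params     = "list"
  )
)

setValidity("Scene", function(object) {
  if (length(object@channels) == 0) return("at least one channel required")
  d <- dim(object@channels[[1]])
  for (nm in names(object@channels)) {
    ch <- object@channels[[nm]]
    if (!is.matrix(ch)) return("channels must be matrices")
    if (!identical(dim(ch), d)) return("all channels must share the grid")
    if (any(ch < 0, na.rm = TRUE)) return(sprintf("channel %s has negative values", nm))
  }
  if (object@pixelScale <= 0) return("pixelScale must be positive")
  if (length(object@origin) != 2L) return("origin must be length 2")
  TRUE
})

#' Acquisition metadata for one tile series
#'
#' Describes how a raw proximal-end tile stack was (or is to be) recorded:
#' stage positions, incoupling drift, scan geometry, channel, per-channel
#' excitation exponent and the noise model.
#'
#' @slot stagePositions n x 2 matrix of stage offsets (um, sample plane)
#' @slot driftPerTile incoupling drift per tile (um, facet plane), length 2
#' @slot driftModel "linear" (default) or "walk" (seeded random walk of the
#'   same expected total magnitude)
#' @slot dwellTime pixel dwell time (us)
#' @slot averages frame averages per tile
#' @slot nx,ny raster size (px)
#' @slot pixelScale um per raster pixel at the fiber facet
#' @slot channel one of "CARS", "SHG", "TPEF"
#' @slot excitationExponent exponent p mapping core transmission t to signal
#'   throughput t^p (CARS default 3: two pump + one Stokes photon; SHG/TPEF
#'   default 2)
#' @slot photonsPerUnit detected photons at unit signal (Poisson scale);
#'   Inf disables shot noise
#' @slot readSigma Gaussian read-noise s.d. (signal units per frame)
#' @slot background dark inter-core raster level (signal units)
#' @slot magnification sample / facet magnification
#' @slot spotFwhm effective excitation spot FWHM at the sample (um)
#' @slot seed integer seed; tile t uses stream (seed, t)
#' @exportClass AcquisitionMeta
setClass("AcquisitionMeta",
  slots = c(
    stagePositions     = "matrix",
    driftPerTile       = "numeric",
    driftModel         = "character",
    dwellTime          = "numeric",
    averages           = "integer",
    nx                 = "integer",
    ny                 = "integer",
    pixelScale         = "numeric",
    channel            = "character",
    excitationExponent = "numeric",
    photonsPerUnit     = "numeric",
    readSigma          = "numeric",
    background         = "numeric",
    magnification      = "numeric",
    spotFwhm           = "numeric",
    seed               = "integer"
  )
)

setValidity("AcquisitionMeta", function(object) {
  if (ncol(object@stagePositions) != 2L)
    return("stagePositions must be an n x 2 matrix")
  if (object@nx <= 0L || object@ny <= 0L) return("nx, ny must be positive")
  if (object@pixelScale <= 0) return("pixelScale must be positive")
  if (!object@channel %in% c("CARS", "SHG", "TPEF"))
    return("channel must be one of CARS, SHG, TPEF")
  if (object@excitationExponent < 1) return("excitationExponent must be >= 1")
  if (object@photonsPerUnit <= 0) return("photonsPerUnit must be positive")
  if (object@readSigma < 0) return("readSigma must be >= 0")
  if (object@averages < 1L) return("averages must be >= 1")
  if (!object@driftModel %in% c("linear", "walk"))
    return("driftModel must be 'linear' or 'walk'")
  TRUE
})

#' @param stagePositions,channel,driftPerTile,driftModel,dwellTime,averages,nx,ny,pixelScale,excitationExponent,photonsPerUnit,readSigma,background,magnification,spotFwhm,seed
#'   see the corresponding slots; `excitationExponent`, `photonsPerUnit` and
#'   `readSigma` default per channel (CARS: p = 3, 250 photons, 0.025; SHG and
#'   TPEF: p = 2, 60 photons, 0.06).
#' @rdname AcquisitionMeta-class
#' @export
AcquisitionMeta <- function(stagePositions = matrix(0, 1, 2),
                            channel = c("CARS", "SHG", "TPEF"),
                            driftPerTile = c(0, 0),
                            driftModel = "linear",
                            dwellTime = 2, averages = 4L,
                            nx = 256L, ny = 256L, pixelScale = 0.55,
                            excitationExponent = NULL,
                            photonsPerUnit = NULL, readSigma = NULL,
                            background = 0.01,
                            magnification = 1.17,
                            spotFwhm = 3.3, seed = 1L) {
  channel <- match.arg(channel)
  if (is.null(excitationExponent))
    excitationExponent <- if (channel == "CARS") 3 else 2
  if (is.null(photonsPerUnit))
    photonsPerUnit <- if (channel == "CARS") 250 else 60
  if (is.null(readSigma))
    readSigma <- if (channel == "CARS") 0.025 else 0.06
  if (!is.matrix(stagePositions))
    stagePositions <- matrix(stagePositions, ncol = 2)
  new("AcquisitionMeta",
      stagePositions = stagePositions, channel = channel,
      driftPerTile = driftPerTile, driftModel = driftModel,
      dwellTime = dwellTime, averages = as.integer(averages),
      nx = as.integer(nx), ny = as.integer(ny), pixelScale = pixelScale,
      excitationExponent = excitationExponent,
      photonsPerUnit = photonsPerUnit, readSigma = readSigma,
      background = background, magnification = magnification,
      spotFwhm = spotFwhm, seed = as.integer(seed))
}

#' A stack of raw (or processed) single-channel tiles
#'
#' @slot tiles ordered list of numeric matrices sharing dimensions; NA marks
#'   invalid pixels
#' @slot meta the [AcquisitionMeta-class]; `meta@pixelScale` tracks the current
#'   grid (it changes when the stack is downscaled)
#' @slot coreMap the [CoreMap-class] used by the simulator, or NULL for
#'   real data
#' @slot driftTrace n x 2 ground-truth accumulated incoupling drift (um);
#'   zero-row matrix when unknown
#' @exportClass TileStack
setClass("TileStack",
  slots = c(
    tiles      = "list",
    meta       = "AcquisitionMeta",
    coreMap    = "ANY",
    driftTrace = "matrix"
  )
)

setValidity("TileStack", function(object) {
  if (length(object@tiles) == 0) return("at least one tile required")
  d <- dim(object@tiles[[1]])
  for (t in object@tiles)
    if (!identical(dim(t), d)) return("all tiles must share dimensions")
  if (length(object@tiles) != nrow(object@meta@stagePositions))
    return(sprintf("tile count (%d) must match stage-position count (%d)",
                   length(object@tiles), nrow(object@meta@stagePositions)))
  if (!is.null(object@coreMap) && !is(object@coreMap, "CoreMap"))
    return("coreMap must be a CoreMap or NULL")
  TRUE
})

#' Per-pixel local transmission-efficiency estimate
#'
#' The per-pixel median across a (downscaled, aligned) tile stack, used as a
#' flat-field reference: dividing each tile by this map removes the per-core
#' transmission pattern without an external reference measurement.
#'
#' @slot values numeric matrix of per-pixel medians
#' @slot frames number of frames the median was taken over
#' @slot pixelScale um per pixel of the map grid
#' @exportClass EfficiencyMap
setClass("EfficiencyMap",
  slots = c(values = "matrix", frames = "integer", pixelScale = "numeric")
)

setValidity("EfficiencyMap", function(object) {
  if (any(object@values < 0, na.rm = TRUE)) return("values must be non-negative")
  if (object@frames < 1L) return("frames must be >= 1")
  TRUE
})

#' Bounded frame buffer for a running median efficiency map
#'
#' Holds the last `window` frames; [medianProjection()] of the buffer gives the
#' current automatic-calibration flat-field map. A buffer may be seeded with
#' frames from a previous measurement session.
#'
#' @slot frames list of numeric matrices (oldest first)
#' @slot window maximum number of retained frames
#' @slot pixelScale um per pixel
#' @exportClass RunningMedianBuffer
setClass("RunningMedianBuffer",
  slots = c(frames = "list", window = "integer", pixelScale = "numeric")
)

setValidity("RunningMedianBuffer", function(object) {
  if (object@window < 1L) return("window must be >= 1")
  if (length(object@frames) > object@window)
    return("buffer holds more frames than its window")
  TRUE
})

#' @param window window size (frames); the workflow default keeps the last 100
#' @param pixelScale um per pixel
#' @rdname RunningMedianBuffer-class
#' @export
RunningMedianBuffer <- function(window = 100L, pixelScale = 1) {
  new("RunningMedianBuffer", frames = list(), window = as.integer(window),
      pixelScale = pixelScale)
}

#' Reconstruction pipeline configuration
#'
#' Every tunable of the depixelation workflow. `NA` cut-offs are resolved at
#' run time: the small cut defaults to 1.5 x the core spacing in the sample
#' plane, the large cut to the tile extent.
#'
#' @slot samplingPxPerSpacing pixels retained per core-to-core distance after
#'   downscaling (default 2 x 2.3 = 4.6: 2.3 samples the lattice at Nyquist,
#'   the factor 2 absorbs diameter variation and imperfect packing)
#' @slot magnification sample / facet magnification applied during stitching
#' @slot blend overlap compositing mode ("linear")
#' @slot bandpassSmallCutUm,bandpassLargeCutUm passed spatial periods (um)
#' @slot keepDC keep the zero-frequency bin (preserves the global mean)
#' @slot efficiencyFloor mask pixels whose efficiency-map value falls below
#'   this fraction of the map's median (protects dead cores and inter-core
#'   gaps from division blow-up)
#' @slot alignReference "first", "previous" or "running"
#' @slot alignUpsample subpixel refinement factor for phase correlation
#' @slot alignThreshold minimum normalized correlation peak; below it a tile
#'   keeps the identity offset and is flagged
#' @slot runningMedianWindow frames kept by the running median (default 100)
#' @slot seed integer seed for any stochastic step
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  slots = c(
    samplingPxPerSpacing = "numeric",
    magnification        = "numeric",
    blend                = "character",
    bandpassSmallCutUm   = "numeric",
    bandpassLargeCutUm   = "numeric",
    keepDC               = "logical",
    efficiencyFloor      = "numeric",
    alignReference       = "character",
    alignUpsample        = "integer",
    alignThreshold       = "numeric",
    runningMedianWindow  = "integer",
    seed                 = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  if (object@samplingPxPerSpacing < 2)
    return("samplingPxPerSpacing must be >= 2 (Nyquist)")
  if (!is.na(object@bandpassSmallCutUm) && !is.na(object@bandpassLargeCutUm) &&
      object@bandpassSmallCutUm >= object@bandpassLargeCutUm)
    return("bandpassSmallCutUm must be < bandpassLargeCutUm")
  if (object@efficiencyFloor <= 0 || object@efficiencyFloor > 1)
    return("efficiencyFloor must lie in (0, 1]")
  if (!object@blend %in% "linear") return("blend must be 'linear'")
  if (!object@alignReference %in% c("first", "previous", "running"))
    return("alignReference must be 'first', 'previous' or 'running'")
  if (object@alignUpsample < 1L) return("alignUpsample must be >= 1")
  TRUE
})

#' @param samplingPxPerSpacing,magnification,blend,bandpassSmallCutUm,bandpassLargeCutUm,keepDC,efficiencyFloor,alignReference,alignUpsample,alignThreshold,runningMedianWindow,seed
#'   see the corresponding slots.
#' @rdname PipelineConfig-class
#' @export
PipelineConfig <- function(samplingPxPerSpacing = 2 * 2.3, magnification = 1.17,
                           blend = "linear",
                           bandpassSmallCutUm = NA_real_,
                           bandpassLargeCutUm = NA_real_,
                           keepDC = TRUE, efficiencyFloor = 0.05,
                           alignReference = "first", alignUpsample = 20L,
                           alignThreshold = 0.01,
                           runningMedianWindow = 100L, seed = 1L) {
  new("PipelineConfig",
      samplingPxPerSpacing = samplingPxPerSpacing, magnification = magnification,
      blend = blend, bandpassSmallCutUm = bandpassSmallCutUm,
      bandpassLargeCutUm = bandpassLargeCutUm, keepDC = keepDC,
      efficiencyFloor = efficiencyFloor, alignReference = alignReference,
      alignUpsample = as.integer(alignUpsample), alignThreshold = alignThreshold,
      runningMedianWindow = as.integer(runningMedianWindow),
      seed = as.integer(seed))
}

#' Stitched mosaic image in sample coordinates
#'
#' @slot image numeric matrix (NA where undefined)
#' @slot weight accumulated blend weight per pixel (0 where uncovered)
#' @slot pixelScale um per mosaic pixel (sample plane)
#' @slot origin sample coordinate (x, y) of the centre of pixel (1, 1), um
#' @slot channel channel label
#' @slot tileOrigins n x 2 matrix of tile centre positions (um)
#' @exportClass Mosaic
setClass("Mosaic",
  slots = c(
    image       = "matrix",
    weight      = "matrix",
    pixelScale  = "numeric",
    origin      = "numeric",
    channel     = "character",
    tileOrigins = "matrix"
  )
)

setValidity("Mosaic", function(object) {
  if (!identical(dim(object@image), dim(object@weight)))
    return("image and weight must share dimensions")
  if (any(object@weight[!is.na(object@image)] <= 0))
    return("weight must be positive wherever the image is defined")
  if (object@pixelScale <= 0) return("pixelScale must be positive")
  TRUE
})

#' Averaged intensity profile along a rectangular ROI
#'
#' @slot positions positions along the long axis (um), strictly increasing
#' @slot intensities mean intensity across the short axis at each position
#' @slot normalized whether intensities were min-max normalized to [0, 1]
#' @exportClass LineProfile
setClass("LineProfile",
  slots = c(positions = "numeric", intensities = "numeric",
            normalized = "logical")
)

setValidity("LineProfile", function(object) {
  if (length(object@positions) != length(object@intensities))
    return("positions and intensities must have equal length")
  if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
    return("positions must be strictly increasing")
  if (object@normalized &&
      (any(object@intensities < -1e-9) || any(object@intensities > 1 + 1e-9)))
    return("normalized intensities must lie in [0, 1]")
  TRUE
})
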