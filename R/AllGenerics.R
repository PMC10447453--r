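## Generics and accessors. Slot access from user code goes through these.

#' @rdname CoreMap-class
#' @param object,x a fibrescope object
#' @export
setGeneric("nCores", function(object) standardGeneric("nCores"))
#' @rdname CoreMap-class
#' @export
setGeneric("coreCenters", function(object) standardGeneric("coreCenters"))
#' @rdname CoreMap-class
#' @export
setGeneric("coreDiameters", function(object) standardGeneric("coreDiameters"))
#' @rdname CoreMap-class
#' @export
setGeneric("coreTransmissions", function(object) standardGeneric("coreTransmissions"))
#' @rdname CoreMap-class
#' @export
setGeneric("bundleSpec", function(object) standardGeneric("bundleSpec"))

#' @rdname TileStack-class
#' @export
setGeneric("tiles", function(object) standardGeneric("tiles"))
#' @rdname TileStack-class
#' @export
setGeneric("nTiles", function(object) standardGeneric("nTiles"))
#' @rdname TileStack-class
#' @export
setGeneric("stagePositions", function(object) standardGeneric("stagePositions"))
#' @rdname TileStack-class
#' @export
setGeneric("driftTrace", function(object) standardGeneric("driftTrace"))
#' @rdname TileStack-class
#' @export
setGeneric("acquisitionMeta", function(object) standardGeneric("acquisitionMeta"))

#' Pixel scale (um per pixel) of an image-bearing object
#' @param object a Scene, TileStack, EfficiencyMap or Mosaic
#' @export
setGeneric("pixelScale", function(object) standardGeneric("pixelScale"))

#' @rdname Scene-class
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))
#' @rdname Scene-class
#' @param channel channel label
#' @export
setGeneric("sceneChannel", function(object, channel) standardGeneric("sceneChannel"))

#' @rdname EfficiencyMap-class
#' @export
setGeneric("efficiencyValues", function(object) standardGeneric("efficiencyValues"))

#' Per-pixel median projection across a stack of frames
#'
#' The per-pixel median across the frames of a [TileStack-class] or a
#' [RunningMedianBuffer-class] estimates the local transmission efficiency of
#' each fiber core: structures of the imaged sample move between tiles while
#' the core pattern is static, so the temporal median retains the pattern and
#' rejects the scene.
#'
#' @param object a TileStack (>= 1 tile; >= 3 recommended) or a non-empty
#'   RunningMedianBuffer
#' @return an [EfficiencyMap-class]
#' @export
setGeneric("medianProjection", function(object) standardGeneric("medianProjection"))

#' @rdname Mosaic-class
#' @export
setGeneric("mosaicImage", function(object) standardGeneric("mosaicImage"))
#' @rdname Mosaic-class
#' @export
setGeneric("weightMap", function(object) standardGeneric("weightMap"))

## ---- accessor methods -------------------------------------------------------

#' @rdname CoreMap-class
#' @export
setMethod("nCores", "CoreMap", function(object) nrow(object@centers))
#' @rdname CoreMap-class
#' @export
setMethod("coreCenters", "CoreMap", function(object) object@centers)
#' @rdname CoreMap-class
#' @export
setMethod("coreDiameters", "CoreMap", function(object) object@diameters)
#' @rdname CoreMap-class
#' @export
setMethod("coreTransmissions", "CoreMap", function(object) object@transmissions)
#' @rdname CoreMap-class
#' @export
setMethod("bundleSpec", "CoreMap", function(object) object@spec)

#' @rdname TileStack-class
#' @export
setMethod("tiles", "TileStack", function(object) object@tiles)
#' @rdname TileStack-class
#' @export
setMethod("nTiles", "TileStack", function(object) length(object@tiles))
#' @rdname TileStack-class
#' @export
setMethod("stagePositions", "TileStack", function(object) object@meta@stagePositions)
#' @rdname TileStack-class
#' @export
setMethod("driftTrace", "TileStack", function(object) object@driftTrace)
#' @rdname TileStack-class
#' @export
setMethod("acquisitionMeta", "TileStack", function(object) object@meta)

#' @rdname pixelScale
#' @export
setMethod("pixelScale", "Scene", function(object) object@pixelScale)
#' @rdname pixelScale
#' @export
setMethod("pixelScale", "TileStack", function(object) object@meta@pixelScale)
#' @rdname pixelScale
#' @export
setMethod("pixelScale", "EfficiencyMap", function(object) object@pixelScale)
#' @rdname pixelScale
#' @export
setMethod("pixelScale", "Mosaic", function(object) object@pixelScale)

#' @rdname Scene-class
#' @export
setMethod("channelNames", "Scene", function(object) names(object@channels))
#' @rdname Scene-class
#' @export
setMethod("sceneChannel", "Scene", function(object, channel) {
  if (!channel %in% names(object@channels))
    stop("unknown channel '", channel, "'; scene has: ",
         paste(names(object@channels), collapse = ", "))
  object@channels[[channel]]
})

#' @rdname EfficiencyMap-class
#' @export
setMethod("efficiencyValues", "EfficiencyMap", function(object) object@values)

#' @rdname Mosaic-class
#' @export
setMethod("mosaicImage", "Mosaic", function(object) object@image)
#' @rdname Mosaic-class
#' @export
setMethod("weightMap", "Mosaic", function(object) object@weight)

## ---- show methods -----------------------------------------------------------

setMethod("show", "BundleSpec", function(object) {
  cat("BundleSpec:", object@imagingDiameter, "um imaging circle,",
      object@meanCoreDistance, "um core spacing,\n  core diameters",
      object@coreDiameterMin, "-", object@coreDiameterMax,
      "um, jitter", object@latticeJitterFrac, "x spacing, transmission CV",
      object@transmissionCV, ", dead fraction", object@deadCoreFrac, "\n")
})

setMethod("show", "CoreMap", function(object) {
  cat("CoreMap with", nCores(object), "cores (seed", object@seed, ")\n")
  if (nCores(object) >= 2) {
    s <- nearestNeighborStats(object)
    cat("  nearest-neighbour distance:", s$mean, "um (sd",
        format(s$sd, digits = 3), ")\n")
  }
  cat("  dead cores:", sum(object@transmissions == 0), "\n")
})

setMethod("show", "Scene", function(object) {
  d <- dim(object@channels[[1]])
  cat("Scene (", object@provenance, "): ", d[2], " x ", d[1], " px at ",
      object@pixelScale, " um/px; channels: ",
      paste(names(object@channels), collapse = ", "), "\n", sep = "")
})

setMethod("show", "TileStack", function(object) {
  d <- dim(object@tiles[[1]])
  cat("TileStack:", nTiles(object), "tiles of", d[2], "x", d[1], "px at",
      signif(object@meta@pixelScale, 4), "um/px, channel",
      object@meta@channel, "\n")
})

setMethod("show", "EfficiencyMap", function(object) {
  d <- dim(object@values)
  cat("EfficiencyMap:", d[2], "x", d[1], "px, median of", object@frames,
      "frames\n")
})

setMethod("show", "Mosaic", function(object) {
  d <- dim(object@image)
  cat("Mosaic (", object@channel, "): ", d[2], " x ", d[1], " px at ",
      signif(object@pixelScale, 4), " um/px; ",
      sum(!is.na(object@image)), " covered pixels\n", sep = "")
})

setMethod("show", "LineProfile", function(object) {
  cat("LineProfile:", length(object@positions), "positions spanning",
      signif(diff(range(object@positions)), 4), "um",
      if (object@normalized) "(normalized)" else "", "\n")
})
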