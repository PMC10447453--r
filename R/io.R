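## Formats: multi-page TIFF tile stacks with JSON/CSV metadata, mosaic
## output, run manifests. TIFF samples are stored as 32-bit values scaled to
## [0, 1]; the affine intensity scale is recorded in the metadata/manifest so
## physical values round-trip (quantization ~2^-32 relative).

.metaToList <- function(meta) {
  list(
    stage_x_um = meta@stagePositions[, 1],
    stage_y_um = meta@stagePositions[, 2],
    drift_per_tile_um = meta@driftPerTile,
    drift_model = meta@driftModel,
    dwell_us = meta@dwellTime, averages = meta@averages,
    nx = meta@nx, ny = meta@ny,
    pixel_scale_um = meta@pixelScale, channel = meta@channel,
    excitation_exponent = meta@excitationExponent,
    photons_at_unit_signal = meta@photonsPerUnit,
    read_sigma = meta@readSigma, background = meta@background,
    magnification = meta@magnification, spot_fwhm_um = meta@spotFwhm,
    seed = meta@seed)
}

.listToMeta <- function(m) {
  AcquisitionMeta(
    stagePositions = cbind(m$stage_x_um, m$stage_y_um),
    channel = m$channel,
    driftPerTile = as.numeric(m$drift_per_tile_um),
    driftModel = m$drift_model %||% "linear",
    dwellTime = m$dwell_us, averages = m$averages,
    nx = m$nx, ny = m$ny, pixelScale = m$pixel_scale_um,
    excitationExponent = m$excitation_exponent,
    photonsPerUnit = if (is.null(m$photons_at_unit_signal) ||
                         is.character(m$photons_at_unit_signal)) Inf
                     else m$photons_at_unit_signal,
    readSigma = m$read_sigma, background = m$background,
    magnification = m$magnification, spotFwhm = m$spot_fwhm_um,
    seed = m$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / load a tile stack as multi-page TIFF plus metadata
#'
#' The image file is a multi-page TIFF (32-bit samples, intensities scaled to
#' [0, 1] with the scale recorded in the metadata). Metadata is JSON
#' (`.json`: the full acquisition record) or CSV (`.csv`: one row per tile
#' with `tile`, `stage_x_um`, `stage_y_um` and per-run constants repeated per
#' row). Both encodings load to the identical stack.
#'
#' @param stack a [TileStack-class]
#' @param imagePath output TIFF path
#' @param metaPath output metadata path (`.json` or `.csv`)
#' @return `writeTileStack`: `imagePath`, invisibly; `loadTileStack`: a
#'   [TileStack-class]
#' @export
writeTileStack <- function(stack, imagePath, metaPath) {
  tl <- tiles(stack)
  lo <- min(vapply(tl, min, numeric(1), na.rm = TRUE), 0)
  hi <- max(vapply(tl, max, numeric(1), na.rm = TRUE))
  if (hi <= lo) hi <- lo + 1
  scaled <- lapply(tl, function(t) {
    t[!is.finite(t)] <- lo
    (t - lo) / (hi - lo)
  })
  tiff::writeTIFF(scaled, imagePath, bits.per.sample = 32L,
                  compression = "none")
  m <- .metaToList(stack@meta)
  m$intensity_offset <- lo
  m$intensity_scale <- hi - lo
  if (grepl("\\.csv$", metaPath, ignore.case = TRUE)) {
    df <- data.frame(tile = seq_len(nTiles(stack)),
                     stage_x_um = m$stage_x_um, stage_y_um = m$stage_y_um)
    for (nm in setdiff(names(m), c("stage_x_um", "stage_y_um"))) {
      v <- m[[nm]]
      if (length(v) == 2)
        v <- paste(format(v, digits = 17), collapse = ";")
      df[[nm]] <- if (is.numeric(v)) v else as.character(v)
    }
    utils::write.csv(df, metaPath, row.names = FALSE)
  } else {
    jsonlite::write_json(m, metaPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(imagePath)
}

#' @rdname writeTileStack
#' @export
loadTileStack <- function(imagePath, metaPath) {
  pages <- tiff::readTIFF(imagePath, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  if (grepl("\\.csv$", metaPath, ignore.case = TRUE)) {
    df <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
    splitPair <- function(s) as.numeric(strsplit(as.character(s), ";")[[1]])
    m <- as.list(df[1, setdiff(names(df), c("tile", "stage_x_um", "stage_y_um"))])
    m$drift_per_tile_um <- splitPair(m$drift_per_tile_um)
    m$stage_x_um <- df$stage_x_um
    m$stage_y_um <- df$stage_y_um
  } else {
    m <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  }
  if (is.null(m$pixel_scale_um) || !is.finite(as.numeric(m$pixel_scale_um)))
    stop("metadata is missing the pixel scale (pixel_scale_um)")
  if (is.null(m$channel) || !m$channel %in% c("CARS", "SHG", "TPEF"))
    stop("unknown channel label '", m$channel %||% "<missing>",
         "'; expected CARS, SHG or TPEF")
  nMeta <- length(m$stage_x_um)
  if (length(pages) != nMeta)
    stop("image has ", length(pages), " page(s) but metadata lists ", nMeta,
         " tile(s)")
  off <- m$intensity_offset %||% 0
  sc <- m$intensity_scale %||% 1
  tl <- lapply(pages, function(p) p * sc + off)
  meta <- .listToMeta(m)
  new("TileStack", tiles = tl, meta = meta, coreMap = NULL,
      driftTrace = matrix(numeric(0), 0, 2))
}

#' Save a reconstruction result to disk
#'
#' Writes one 32-bit TIFF per channel mosaic (intensity scale recorded in the
#' manifest, resolution expressed as a `pixel_scale_um` manifest entry), an
#' 8-bit RGB composite PNG when available, and the run manifest JSON.
#'
#' @param result a [Mosaic-class] or the list returned by [runPipeline()]
#' @param outDir output directory (created if needed)
#' @return named character vector of written files, invisibly
#' @export
saveMosaic <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  writeOne <- function(mos, name) {
    img <- mos@image
    lo <- min(img, 0, na.rm = TRUE); hi <- max(img, na.rm = TRUE)
    if (hi <= lo) hi <- lo + 1
    x <- (img - lo) / (hi - lo)
    x[!is.finite(x)] <- 0
    p <- file.path(outDir, paste0(name, ".tiff"))
    tiff::writeTIFF(x, p, bits.per.sample = 32L, compression = "none")
    list(path = p, offset = lo, scale = hi - lo,
         pixel_scale_um = mos@pixelScale, origin_um = mos@origin,
         channel = mos@channel)
  }
  manifest <- list(files = list())
  if (is(result, "Mosaic")) {
    info <- writeOne(result, paste0("mosaic_", result@channel))
    files[info$channel] <- info$path
    manifest$files[[info$channel]] <- info
  } else if (is.null(result$mosaics)) {
    info <- writeOne(result$mosaic, paste0("mosaic_", result$mosaic@channel))
    files[info$channel] <- info$path
    manifest$files[[info$channel]] <- info
    manifest$pipeline <- result$manifest
  } else {
    for (ch in names(result$mosaics)) {
      info <- writeOne(result$mosaics[[ch]], paste0("mosaic_", ch))
      files[ch] <- info$path
      manifest$files[[ch]] <- info
    }
    if (!is.null(result$composite)) {
      p <- file.path(outDir, "composite.png")
      png::writePNG(result$composite, p)
      files["composite"] <- p
      manifest$files$composite <- list(
        path = p, scaling = attr(result$composite, "scaling"))
    }
    manifest$pipeline <- result$manifest
  }
  mp <- file.path(outDir, "manifest.json")
  manifest$digests <- as.list(tools::md5sum(unname(files)))
  writeManifest(manifest, mp)
  files["manifest"] <- mp
  invisible(files)
}

#' Load a mosaic written by [saveMosaic()]
#'
#' @param outDir directory written by [saveMosaic()]
#' @param channel channel to load
#' @return a [Mosaic-class]
#' @export
loadMosaic <- function(outDir, channel = "CARS") {
  man <- readManifest(file.path(outDir, "manifest.json"))
  info <- man$files[[channel]]
  if (is.null(info)) stop("manifest has no channel '", channel, "'")
  x <- tiff::readTIFF(file.path(outDir, basename(info$path)))
  img <- x * info$scale + info$offset
  new("Mosaic", image = img, weight = matrix(1, nrow(img), ncol(img)),
      pixelScale = info$pixel_scale_um, origin = as.numeric(info$origin_um),
      channel = channel,
      tileOrigins = matrix(numeric(0), 0, 2))
}

#' Run manifests
#'
#' A run manifest records everything needed to regenerate a result: the
#' configuration echo, every seed, the stage list with parameters, and the
#' package version. [validateManifest()] checks the required fields;
#' manifests round-trip losslessly through JSON.
#'
#' @param cfg a [PipelineConfig-class]
#' @param seeds named numeric vector of all seeds involved
#' @param stages named list of per-stage parameter records
#' @param ... further fields stored verbatim
#' @return `makeRunManifest`: a manifest list
#' @export
makeRunManifest <- function(cfg, seeds, stages, ...) {
  list(
    version = as.character(utils::packageVersion("fibrescope")),
    config = list(
      samplingPxPerSpacing = cfg@samplingPxPerSpacing,
      magnification = cfg@magnification, blend = cfg@blend,
      ## NA cut-offs mean "derived at run time"; serialized as "auto" so the
      ## manifest round-trips losslessly through JSON
      bandpassSmallCutUm = if (is.na(cfg@bandpassSmallCutUm)) "auto"
                           else cfg@bandpassSmallCutUm,
      bandpassLargeCutUm = if (is.na(cfg@bandpassLargeCutUm)) "auto"
                           else cfg@bandpassLargeCutUm,
      keepDC = cfg@keepDC, efficiencyFloor = cfg@efficiencyFloor,
      alignReference = cfg@alignReference,
      alignUpsample = cfg@alignUpsample,
      alignThreshold = cfg@alignThreshold,
      runningMedianWindow = cfg@runningMedianWindow, seed = cfg@seed),
    seeds = as.list(seeds),
    stages = stages,
    ...)
}

#' @param manifest a manifest list
#' @param path JSON path
#' @rdname makeRunManifest
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname makeRunManifest
#' @export
readManifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
}

#' @rdname makeRunManifest
#' @export
validateManifest <- function(manifest) {
  required <- c("version", "config", "seeds", "stages")
  missing <- setdiff(required, names(manifest))
  if (length(missing))
    stop("manifest is missing required field(s): ",
         paste(missing, collapse = ", "))
  if (length(manifest$seeds) == 0)
    stop("manifest must record at least one seed")
  invisible(TRUE)
}

#' Parse a pipeline configuration from YAML
#'
#' Reads a YAML mapping whose keys are [PipelineConfig-class] constructor
#' arguments; unknown keys are an error (auditable configs). `overrides`
#' (e.g. parsed command-line flags) take precedence over file values.
#'
#' @param path YAML file, or NULL for defaults
#' @param overrides named list of overriding values
#' @return a [PipelineConfig-class]
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  known <- names(formals(PipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(PipelineConfig, vals)
}
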