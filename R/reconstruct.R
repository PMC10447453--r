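## The depixelation workflow: align -> downscale -> median projection ->
## normalize -> stitch -> FFT bandpass, plus multi-frame shifted superposition.

## ---- phase cross-correlation ------------------------------------------------

## Estimate the translation of `mov` relative to `ref` by spectral cross-
## correlation with subpixel refinement on an upsampled DFT neighbourhood.
## Returns shift = c(dy, dx) such that mov(x) ~ ref(x - shift), plus the
## normalized correlation-peak height.
.phaseCorr <- function(ref, mov, upsample = 1L) {
  a <- ref; a[!is.finite(a)] <- mean(a, na.rm = TRUE); a <- a - mean(a)
  b <- mov; b[!is.finite(b)] <- mean(b, na.rm = TRUE); b <- b - mean(b)
  N1 <- nrow(a); N2 <- ncol(a)
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  CP <- Fa * Conj(Fb)
  mag <- Mod(CP)
  R <- CP / ifelse(mag > .Machine$double.eps, mag, 1)
  cc <- Re(stats::fft(R, inverse = TRUE)) / (N1 * N2)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ## cross-power peak sits at -shift (mod N)
  py <- pk[1] - 1; px <- pk[2] - 1
  if (py > N1 / 2) py <- py - N1
  if (px > N2 / 2) px <- px - N2
  peakHeight <- max(cc)
  shift <- c(-py, -px)
  if (upsample > 1L) {
    f1 <- c(0:floor(N1 / 2), -((ceiling(N1 / 2) - 1):1))
    f2 <- c(0:floor(N2 / 2), -((ceiling(N2 / 2) - 1):1))
    y1 <- py + seq(-1, 1, by = 1 / upsample)
    y2 <- px + seq(-1, 1, by = 1 / upsample)
    E1 <- exp(2i * pi * outer(y1, f1) / N1)          # nY1 x N1
    E2 <- exp(2i * pi * outer(f2, y2) / N2)          # N2 x nY2
    ccf <- Re(E1 %*% R %*% E2) / (N1 * N2)
    pk2 <- which(ccf == max(ccf), arr.ind = TRUE)[1, ]
    shift <- c(-y1[pk2[1]], -y2[pk2[2]])
    peakHeight <- max(ccf)
  }
  list(shift = shift, peak = peakHeight)
}

#' Align a tile stack to a common core-lattice position
#'
#' Raw stacks drift by about one core-to-core distance per 100 tiles because
#' the laser incoupling conditions vary; alignment translates every tile so
#' that the core lattice coincides with the reference. Offsets are estimated
#' by spectral (phase) cross-correlation with subpixel refinement by local
#' DFT upsampling, and applied by bilinear resampling (NA fill at the edges).
#' Tiles whose correlation peak falls below `cfg@alignThreshold` keep the
#' identity offset and are flagged with a warning.
#'
#' @param stack a [TileStack-class]
#' @param cfg a [PipelineConfig-class] (`alignReference`, `alignUpsample`,
#'   `alignThreshold`)
#' @return list with `stack` (aligned [TileStack-class]), `offsets` (n x 2
#'   matrix of applied corrections, columns `dy`, `dx`, px) and `flagged`
#'   (logical vector)
#' @export
alignStack <- function(stack, cfg = PipelineConfig()) {
  n <- nTiles(stack)
  tl <- tiles(stack)
  offsets <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
  flagged <- logical(n)
  if (n > 1) {
    prevShift <- c(0, 0)
    runRef <- tl[[1]]
    for (t in 2:n) {
      ref <- switch(cfg@alignReference,
                    first = tl[[1]],
                    previous = tl[[t - 1]],
                    running = runRef)
      pc <- .phaseCorr(ref, tl[[t]], cfg@alignUpsample)
      if (pc$peak < cfg@alignThreshold) {
        flagged[t] <- TRUE
        sh <- c(0, 0)
      } else sh <- pc$shift
      total <- if (cfg@alignReference == "previous") prevShift + sh else sh
      if (cfg@alignReference == "previous") prevShift <- total
      offsets[t, ] <- -total
      tl[[t]] <- .translate(tl[[t]], -total[1], -total[2])
      if (cfg@alignReference == "running") {
        w <- 1 / t
        filled <- ifelse(is.na(tl[[t]]), runRef, tl[[t]])
        runRef <- (1 - w) * runRef + w * filled
      }
    }
    if (any(flagged))
      warning(sum(flagged), " tile(s) below the correlation threshold; ",
              "identity offset used")
  }
  out <- stack
  out@tiles <- tl
  list(stack = out, offsets = offsets, flagged = flagged)
}

#' Downscale a stack to the target core sampling
#'
#' Raw tiles are strongly oversampled; processing only needs
#' `cfg@samplingPxPerSpacing` pixels per core-to-core centre distance
#' (default 2 x 2.3 = 4.6: 2.3 samples the lattice at Nyquist and the factor
#' 2 absorbs core-diameter variation and imperfect packing). Rescaling uses
#' area averaging, which preserves the mean intensity (flux) feeding the
#' subsequent division step. If the stack is already at or below the target
#' sampling the stack is returned unchanged with a warning.
#'
#' @param stack a [TileStack-class]
#' @param spacingPx core spacing on the current grid (px); estimated from the
#'   first tile with [estimateCoreSpacing()] when NULL
#' @param cfg a [PipelineConfig-class]
#' @return a [TileStack-class] on the coarser grid (meta updated)
#' @export
downscaleStack <- function(stack, spacingPx = NULL, cfg = PipelineConfig()) {
  if (is.null(spacingPx))
    spacingPx <- estimateCoreSpacing(tiles(stack)[[1]])$spacing_px
  if (spacingPx <= 0) stop("spacingPx must be positive")
  factor <- cfg@samplingPxPerSpacing / spacingPx
  if (factor >= 1) {
    warning("stack already at or below ", cfg@samplingPxPerSpacing,
            " px per core spacing; downscaling skipped")
    return(stack)
  }
  tl <- lapply(tiles(stack), .resizeArea, factor = factor)
  d <- dim(tl[[1]])
  meta <- stack@meta
  ## actual factor after rounding the target size
  fEff <- mean(c(d[1] / meta@ny, d[2] / meta@nx))
  meta@ny <- d[1]; meta@nx <- d[2]
  meta@pixelScale <- meta@pixelScale / fEff
  out <- stack
  out@tiles <- tl
  out@meta <- meta
  out
}

## ---- median projection / flat-field -----------------------------------------

.stackMedian <- function(tilesList) {
  arr <- simplify2array(tilesList)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  apply(arr, c(1, 2), stats::median, na.rm = TRUE)
}

#' @rdname medianProjection
#' @export
setMethod("medianProjection", "TileStack", function(object) {
  new("EfficiencyMap", values = pmax(.stackMedian(tiles(object)), 0),
      frames = nTiles(object), pixelScale = pixelScale(object))
})

#' @rdname medianProjection
#' @export
setMethod("medianProjection", "RunningMedianBuffer", function(object) {
  if (length(object@frames) == 0) stop("running-median buffer is empty")
  new("EfficiencyMap", values = pmax(.stackMedian(object@frames), 0),
      frames = length(object@frames), pixelScale = object@pixelScale)
})

#' Push a frame into a running-median buffer
#'
#' Keeps at most `window` frames, evicting the oldest at capacity. The
#' resulting [medianProjection()] tracks slow drifts of the incoupling
#' efficiency (automatic calibration); a buffer seeded from a previous
#' session is a valid starting point.
#'
#' @param buffer a [RunningMedianBuffer-class]
#' @param frame numeric matrix matching the buffered dimensions
#' @return the updated buffer
#' @export
updateRunningMedian <- function(buffer, frame) {
  if (length(buffer@frames) > 0 &&
      !identical(dim(frame), dim(buffer@frames[[1]])))
    stop("frame dimensions (", paste(dim(frame), collapse = " x "),
         ") do not match buffered frames (",
         paste(dim(buffer@frames[[1]]), collapse = " x "), ")")
  frames <- c(buffer@frames, list(frame))
  if (length(frames) > buffer@window)
    frames <- frames[-1]
  buffer@frames <- frames
  buffer
}

#' Flat-field normalize a stack by its efficiency map
#'
#' Divides every pixel of every tile by the corresponding efficiency-map
#' pixel, removing the per-core transmission pattern. Map pixels below
#' `cfg@efficiencyFloor` times the map's median are floored in the division
#' and the output there is marked invalid (NA): dead cores and inter-core
#' gaps must not blow up.
#'
#' @param stack a [TileStack-class] (dimensions matching the map)
#' @param map an [EfficiencyMap-class]
#' @param cfg a [PipelineConfig-class]
#' @return a [TileStack-class] of normalized tiles with NA at invalid pixels
#' @export
normalizeStack <- function(stack, map, cfg = PipelineConfig()) {
  m <- map@values
  if (!identical(dim(m), dim(tiles(stack)[[1]])))
    stop("efficiency map dimensions do not match the tiles")
  if (all(m == 0 | !is.finite(m)))
    stop("efficiency map is all zero")
  med <- stats::median(m, na.rm = TRUE)
  floorVal <- cfg@efficiencyFloor * med
  invalid <- !is.finite(m) | m < floorVal
  denom <- pmax(m, floorVal)
  tl <- lapply(tiles(stack), function(t) {
    out <- t / denom
    out[invalid] <- NA_real_
    out
  })
  out <- stack
  out@tiles <- tl
  out
}

## ---- stitching --------------------------------------------------------------

## per-tile linear blending weight: distance to the nearest tile edge
.edgeRamp <- function(nr, nc) {
  wr <- pmin(seq_len(nr), nr + 1 - seq_len(nr))
  wc <- pmin(seq_len(nc), nc + 1 - seq_len(nc))
  outer(wr, wc, pmin)
}

#' Stitch normalized tiles into a mosaic with linear blending
#'
#' Tile coordinates are scaled by the probe magnification (sample site /
#' incoupling site) and placed at their stage positions in sample space.
#' Overlapping areas are blended with weights ramping linearly from each
#' tile's edge; the accumulated weights are normalized so that effective
#' weights sum to one everywhere covered. Invalid (NA) tile pixels get zero
#' weight. Pixels covered by no tile are NA (a warning reports gaps).
#'
#' @param tilesList list of numeric matrices (NA = invalid), equal dimensions
#' @param stagePositionsUm n x 2 matrix of tile-centre stage positions (um)
#' @param pixelScaleUm um per tile pixel at the fiber facet
#' @param cfg a [PipelineConfig-class] (`magnification`, `blend`)
#' @param channel channel label carried into the mosaic
#' @return a [Mosaic-class]
#' @export
stitchMosaic <- function(tilesList, stagePositionsUm, pixelScaleUm,
                         cfg = PipelineConfig(), channel = "CARS") {
  n <- length(tilesList)
  if (n == 0) stop("no tiles to stitch")
  if (!is.matrix(stagePositionsUm))
    stagePositionsUm <- matrix(stagePositionsUm, ncol = 2)
  if (nrow(stagePositionsUm) != n)
    stop("tile count (", n, ") and stage-position count (",
         nrow(stagePositionsUm), ") differ")
  d <- dim(tilesList[[1]])
  nr <- d[1]; nc <- d[2]
  scaleOut <- pixelScaleUm * cfg@magnification

  ## mosaic grid covering all tiles; pixel (1,1) centre at (xmin, ymin)
  cxs <- stagePositionsUm[, 1]; cys <- stagePositionsUm[, 2]
  xmin <- min(cxs) - (nc - 1) / 2 * scaleOut
  ymin <- min(cys) - (nr - 1) / 2 * scaleOut
  xmax <- max(cxs) + (nc - 1) / 2 * scaleOut
  ymax <- max(cys) + (nr - 1) / 2 * scaleOut
  ncOut <- round((xmax - xmin) / scaleOut) + 1L
  nrOut <- round((ymax - ymin) / scaleOut) + 1L

  num <- matrix(0, nrOut, ncOut)
  den <- matrix(0, nrOut, ncOut)
  ramp <- .edgeRamp(nr, nc)
  for (t in seq_len(n)) {
    ## mosaic pixels potentially covered by tile t
    jlo <- max(1L, floor((cxs[t] - (nc - 1) / 2 * scaleOut - xmin) / scaleOut) + 1L)
    jhi <- min(ncOut, ceiling((cxs[t] + (nc - 1) / 2 * scaleOut - xmin) / scaleOut) + 1L)
    ilo <- max(1L, floor((cys[t] - (nr - 1) / 2 * scaleOut - ymin) / scaleOut) + 1L)
    ihi <- min(nrOut, ceiling((cys[t] + (nr - 1) / 2 * scaleOut - ymin) / scaleOut) + 1L)
    jj <- jlo:jhi; ii <- ilo:ihi
    X <- xmin + (jj - 1) * scaleOut
    Y <- ymin + (ii - 1) * scaleOut
    tc <- (X - cxs[t]) / scaleOut + (nc + 1) / 2   # tile col positions
    tr <- (Y - cys[t]) / scaleOut + (nr + 1) / 2   # tile row positions
    TR <- matrix(tr, length(ii), length(jj))
    TC <- matrix(tc, length(ii), length(jj), byrow = TRUE)
    v <- .bilinear(tilesList[[t]], as.vector(TR), as.vector(TC))
    w <- .bilinear(ramp, as.vector(TR), as.vector(TC))
    ok <- is.finite(v) & is.finite(w) & w > 0
    v[!ok] <- 0; w[!ok] <- 0
    num[ii, jj] <- num[ii, jj] + matrix(w * v, length(ii), length(jj))
    den[ii, jj] <- den[ii, jj] + matrix(w, length(ii), length(jj))
  }
  img <- num / den
  img[den == 0] <- NA_real_
  if (any(den == 0))
    warning(sum(den == 0), " mosaic pixel(s) not covered by any tile")
  new("Mosaic", image = img, weight = den, pixelScale = scaleOut,
      origin = c(xmin, ymin), channel = channel,
      tileOrigins = stagePositionsUm)
}

## ---- FFT bandpass -----------------------------------------------------------

#' Annular FFT bandpass filter
#'
#' Removes the residual core-lattice (honeycomb) structure from a mosaic by
#' an annular amplitude filter in the spectral domain: spatial periods inside
#' `[smallCutUm, largeCutUm]` pass, with raised-cosine transitions of total
#' relative width `edgeFrac` centred on each cut-off frequency (half power at
#' the cut-off, the usual filter convention). The zero-frequency bin is kept
#' when `keepDC`, so the global mean is preserved. The filter is a linear
#' operator. NA pixels are filled with the image mean for the transform and
#' restored afterwards.
#'
#' @param image numeric matrix
#' @param pixelScaleUm um per pixel
#' @param smallCutUm smallest passed period (um)
#' @param largeCutUm largest passed period (um); Inf disables the high-pass
#'   side
#' @param keepDC keep the DC bin (preserve the mean)
#' @param edgeFrac raised-cosine transition width as a fraction of each
#'   cut-off frequency
#' @return filtered matrix (NA pattern preserved)
#' @export
fftBandpass <- function(image, pixelScaleUm, smallCutUm, largeCutUm = Inf,
                        keepDC = TRUE, edgeFrac = 0.2) {
  if (smallCutUm >= largeCutUm)
    stop("smallCutUm (", smallCutUm, ") must be < largeCutUm (", largeCutUm, ")")
  nr <- nrow(image); nc <- ncol(image)
  nas <- !is.finite(image)
  x <- image
  fill <- mean(image[!nas])
  x[nas] <- fill
  fy <- c(0:floor(nr / 2), -((ceiling(nr / 2) - 1):1)) / (nr * pixelScaleUm)
  fx <- c(0:floor(nc / 2), -((ceiling(nc / 2) - 1):1)) / (nc * pixelScaleUm)
  FR <- sqrt(outer(fy^2, fx^2, "+"))
  fHigh <- 1 / smallCutUm
  fLow <- if (is.finite(largeCutUm)) 1 / largeCutUm else 0
  H <- matrix(1, nr, nc)
  rampUp <- function(f, fc) {          # 0 below the edge, 1 above, 0.5 at fc
    a <- fc * (1 - edgeFrac / 2); b <- fc * (1 + edgeFrac / 2)
    h <- 0.5 - 0.5 * cos(pi * (f - a) / (b - a))
    h[f <= a] <- 0; h[f >= b] <- 1
    h
  }
  if (fLow > 0) H <- H * rampUp(FR, fLow)
  H <- H * (1 - rampUp(FR, fHigh))
  if (keepDC) H[1, 1] <- 1
  out <- Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / (nr * nc)
  out[nas] <- NA_real_
  out
}

## ---- shifted superposition --------------------------------------------------

#' Superimpose sub-core-shifted frames on an upsampled grid
#'
#' Multiple frames of the same field taken with lateral shifts smaller than
#' the core spacing sample the space between cores; placing them on a common
#' upsampled grid at their shift offsets and averaging per covered pixel
#' reconstructs that space and improves the effective resolution beyond the
#' single-shot lattice limit. Only the region covered by every frame is
#' returned (the rest is cropped).
#'
#' @param tilesList list of numeric matrices (NA = invalid)
#' @param shiftsUm n x 2 matrix of sample-plane shifts (um)
#' @param upsample integer upsampling factor of the output grid
#' @param pixelScaleUm um per tile pixel at the fiber facet
#' @param magnification sample / facet magnification
#' @return a [Mosaic-class] (weight = number of contributing frames)
#' @export
superimposeShifted <- function(tilesList, shiftsUm, upsample = 2L,
                               pixelScaleUm = 1, magnification = 1) {
  n <- length(tilesList)
  if (n == 0) stop("no tiles to superimpose")
  if (!is.matrix(shiftsUm)) shiftsUm <- matrix(shiftsUm, ncol = 2)
  d <- dim(tilesList[[1]])
  nr <- d[1]; nc <- d[2]
  tileScale <- pixelScaleUm * magnification
  scaleOut <- tileScale / upsample
  cxs <- shiftsUm[, 1]; cys <- shiftsUm[, 2]
  xmin <- min(cxs) - (nc - 1) / 2 * tileScale
  ymin <- min(cys) - (nr - 1) / 2 * tileScale
  xmax <- max(cxs) + (nc - 1) / 2 * tileScale
  ymax <- max(cys) + (nr - 1) / 2 * tileScale
  ncOut <- floor((xmax - xmin) / scaleOut) + 1L
  nrOut <- floor((ymax - ymin) / scaleOut) + 1L
  num <- matrix(0, nrOut, ncOut)
  cnt <- matrix(0L, nrOut, ncOut)
  X <- xmin + (seq_len(ncOut) - 1) * scaleOut
  Y <- ymin + (seq_len(nrOut) - 1) * scaleOut
  for (t in seq_len(n)) {
    tc <- (X - cxs[t]) / tileScale + (nc + 1) / 2
    tr <- (Y - cys[t]) / tileScale + (nr + 1) / 2
    TR <- matrix(tr, nrOut, ncOut)
    TC <- matrix(tc, nrOut, ncOut, byrow = TRUE)
    v <- matrix(.bilinear(tilesList[[t]], as.vector(TR), as.vector(TC)),
                nrOut, ncOut)
    ok <- is.finite(v)
    num[ok] <- num[ok] + v[ok]
    cnt <- cnt + ok
  }
  ## geometric intersection of all frame rectangles (the area covered by
  ## every frame); per-pixel invalid (NA) contributions are simply skipped
  ## in the average
  fx <- c(max(cxs) - (nc - 1) / 2 * tileScale, min(cxs) + (nc - 1) / 2 * tileScale)
  fy <- c(max(cys) - (nr - 1) / 2 * tileScale, min(cys) + (nr - 1) / 2 * tileScale)
  if (fx[1] >= fx[2] || fy[1] >= fy[2])
    stop("no region is covered by all frames")
  full <- outer(Y >= fy[1] & Y <= fy[2], X >= fx[1] & X <= fx[2], "&")
  img <- num / cnt
  img[!full | cnt == 0] <- NA_real_
  rows <- range(which(rowSums(full) > 0))
  cols <- range(which(colSums(full) > 0))
  img <- img[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  w <- cnt[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  new("Mosaic", image = img, weight = w + 0, pixelScale = scaleOut,
      origin = c(xmin + (cols[1] - 1) * scaleOut,
                 ymin + (rows[1] - 1) * scaleOut),
      channel = "superposition", tileOrigins = shiftsUm)
}

## ---- full pipeline ----------------------------------------------------------

#' Run the full depixelation workflow on a tile stack
#'
#' Executes the six correction stages in order: (1) stack alignment, (2)
#' downscaling to the target core sampling, (3) median projection, (4)
#' division by the median projection (flat-field normalization), (5) mosaic
#' stitching with linear blending under the probe magnification, (6) annular
#' FFT bandpass removing the residual core structure. Per-stage intermediates
#' are returned for audit. For multi-channel input (a named list of stacks)
#' the per-channel mosaics are composited to RGB with the fixed mapping
#' CARS = red, SHG = blue, TPEF = green.
#'
#' @param stack a [TileStack-class], or a named list of them (one per channel)
#' @param cfg a [PipelineConfig-class]
#' @param efficiency optional [EfficiencyMap-class] from a previous
#'   calibration (e.g. a running median); when given, stage (3) uses it
#'   instead of the stack's own median projection
#' @param intermediates keep per-stage intermediates in the result
#' @return list with `mosaic` (single channel) or `mosaics` + `composite`
#'   (multi channel), `manifest`, and optionally `intermediates`
#' @export
runPipeline <- function(stack, cfg = PipelineConfig(), efficiency = NULL,
                        intermediates = FALSE) {
  if (is.list(stack)) {
    res <- lapply(names(stack), function(ch)
      runPipeline(stack[[ch]], cfg, efficiency = NULL,
                  intermediates = intermediates))
    names(res) <- names(stack)
    mosaics <- lapply(res, `[[`, "mosaic")
    dims <- vapply(mosaics, function(m) dim(m@image), integer(2))
    composite <- NULL
    if (all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1])) {
      get0 <- function(ch) if (ch %in% names(mosaics))
        mosaics[[ch]]@image else matrix(0, dims[1, 1], dims[2, 1])
      composite <- composeRgb(get0("CARS"), get0("SHG"), get0("TPEF"))
    }
    return(list(mosaics = mosaics, composite = composite,
                manifest = lapply(res, `[[`, "manifest"),
                intermediates = if (intermediates)
                  lapply(res, `[[`, "intermediates")))
  }

  stageErr <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  rawScale <- pixelScale(stack)

  al <- stageErr("align", alignStack(stack, cfg))

  spacingPx <- stageErr("downscale", {
    est <- tryCatch(estimateCoreSpacing(tiles(al$stack)[[1]], rawScale),
                    error = function(e) NULL)
    if (!is.null(est)) est$spacing_px
    else if (!is.null(stack@coreMap))
      nearestNeighborStats(stack@coreMap)$mean / rawScale
    else stop("core spacing could not be estimated and no core map is attached")
  })
  ds <- stageErr("downscale", downscaleStack(al$stack, spacingPx, cfg))

  eff <- if (is.null(efficiency)) {
    stageErr("median-projection", medianProjection(ds))
  } else efficiency

  norm <- stageErr("normalize", normalizeStack(ds, eff, cfg))

  mosaic <- stageErr("stitch",
    stitchMosaic(tiles(norm), stagePositions(norm), pixelScale(norm), cfg,
                 channel = norm@meta@channel))

  spacingSampleUm <- spacingPx * rawScale * cfg@magnification
  smallCut <- if (is.na(cfg@bandpassSmallCutUm))
    1.5 * spacingSampleUm else cfg@bandpassSmallCutUm
  largeCut <- if (is.na(cfg@bandpassLargeCutUm))
    max(dim(tiles(norm)[[1]])) * pixelScale(norm) * cfg@magnification
  else cfg@bandpassLargeCutUm
  filtered <- stageErr("bandpass",
    fftBandpass(mosaic@image, mosaic@pixelScale, smallCut, largeCut,
                keepDC = cfg@keepDC))
  out <- mosaic
  out@image <- filtered

  manifest <- makeRunManifest(
    cfg, seeds = c(acquisition = stack@meta@seed, pipeline = cfg@seed),
    stages = list(
      align = list(reference = cfg@alignReference,
                   upsample = cfg@alignUpsample,
                   maxOffsetPx = max(abs(al$offsets)),
                   flagged = sum(al$flagged)),
      downscale = list(spacingPxRaw = spacingPx,
                       sampling = cfg@samplingPxPerSpacing,
                       pixelScaleUm = pixelScale(norm)),
      medianProjection = list(frames = eff@frames,
                              external = !is.null(efficiency)),
      normalize = list(efficiencyFloor = cfg@efficiencyFloor),
      stitch = list(blend = cfg@blend, magnification = cfg@magnification,
                    tiles = nTiles(stack)),
      bandpass = list(smallCutUm = smallCut, largeCutUm = largeCut,
                      keepDC = cfg@keepDC)),
    channel = stack@meta@channel)

  list(mosaic = out, manifest = manifest,
       intermediates = if (intermediates)
         list(offsets = al$offsets, spacingPx = spacingPx, efficiency = eff,
              normalized = norm, prebandpass = mosaic))
}

#' Fill invalid (masked) pixels by normalized convolution
#'
#' Replaces NA pixels with the Gaussian-weighted average of nearby valid
#' pixels (normalized convolution). Masked dead-core areas in a normalized
#' single shot are known-invalid rather than dark; inpainting them this way
#' lets profile-based metrics run across them without biasing the valid
#' pixels, which are returned unchanged.
#'
#' @param image numeric matrix with NA at invalid pixels
#' @param sigmaPx Gaussian weighting sigma (px)
#' @return matrix with invalid pixels filled (NA only where no valid pixel
#'   lies within reach)
#' @export
fillInvalid <- function(image, sigmaPx = 2) {
  bad <- !is.finite(image)
  if (!any(bad)) return(image)
  w <- 1 - bad
  x <- image; x[bad] <- 0
  num <- .gblur(x, sigmaPx)
  den <- .gblur(w, sigmaPx)
  out <- image
  fill <- bad & den > 1e-6
  out[fill] <- num[fill] / den[fill]
  out
}
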