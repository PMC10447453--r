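## Forward model: sample-plane scenes and fiber-bundle tile acquisition.

.newScene <- function(channels, pixelScale, provenance, params) {
  d <- dim(channels[[1]])
  origin <- -c(d[2] - 1, d[1] - 1) / 2 * pixelScale  # centred on (0, 0)
  new("Scene", channels = channels, pixelScale = pixelScale,
      origin = origin, provenance = provenance, params = params)
}

.emptyChannels <- function(nr, nc) {
  z <- matrix(0, nr, nc)
  list(CARS = z, SHG = z, TPEF = z)
}

#' Bead cluster phantom
#'
#' Non-overlapping disks of unit CARS signal density on a low constant
#' background emulating the non-resonant CARS background. Bead edges are
#' antialiased over one scene pixel. Placement is rejection sampling with a
#' bounded number of retries; pass `centers` to place beads deterministically
#' (e.g. bead pairs at a controlled separation).
#'
#' @param diametersUm bead diameters (um), one entry per size class
#' @param counts beads per size class
#' @param windowUm scene window c(width, height) (um)
#' @param minGapUm minimum edge-to-edge gap (0 = densely packed allowed)
#' @param pixelScale scene um/px
#' @param background constant background level
#' @param centers optional n x 2 matrix of explicit centres (um,
#'   window-centred); then `diametersUm` is recycled per bead and
#'   `counts` is ignored
#' @param channel channel carrying the beads (default CARS)
#' @param seed integer seed
#' @return a [Scene-class] with the beads in the requested channel
#' @export
makeBeadPhantom <- function(diametersUm, counts, windowUm = c(210, 210),
                            minGapUm = 0, pixelScale = 0.5,
                            background = 0.05, centers = NULL,
                            channel = "CARS", seed = 1L) {
  if (any(diametersUm <= 0)) stop("diametersUm must be positive")
  nc <- round(windowUm[1] / pixelScale)
  nr <- round(windowUm[2] / pixelScale)
  xs <- (seq_len(nc) - (nc + 1) / 2) * pixelScale
  ys <- (seq_len(nr) - (nr + 1) / 2) * pixelScale

  if (is.null(centers)) {
    placed <- .withSeed(seed, 0L, function()
      .placeBeads(diametersUm, counts, windowUm, minGapUm))
  } else {
    placed <- cbind(centers,
                    rep(diametersUm, length.out = nrow(centers)))
  }
  img <- matrix(background, nr, nc)
  if (nrow(placed) > 0) {
    for (i in seq_len(nrow(placed))) {
      r <- placed[i, 3] / 2
      dx <- xs - placed[i, 1]; dy <- ys - placed[i, 2]
      jj <- which(abs(dx) <= r + pixelScale); ii <- which(abs(dy) <= r + pixelScale)
      if (!length(jj) || !length(ii)) next
      d <- sqrt(outer(dy[ii]^2, dx[jj]^2, "+"))
      cov <- pmin(1, pmax(0, (r - d) / pixelScale + 0.5))
      img[ii, jj] <- pmax(img[ii, jj], background + (1 - background) * cov)
    }
  }
  ch <- .emptyChannels(nr, nc)
  ch[[channel]] <- img
  .newScene(ch, pixelScale, "bead",
            list(diameters = diametersUm,
                 centers = placed[, 1:2, drop = FALSE],
                 placedDiameters = placed[, 3],
                 background = background, seed = seed))
}

.placeBeads <- function(diametersUm, counts, windowUm, minGapUm,
                        maxRetries = 500L) {
  stopifnot(length(diametersUm) == length(counts))
  placed <- matrix(numeric(0), 0, 3)
  for (k in seq_along(diametersUm)) {
    d <- diametersUm[k]
    for (b in seq_len(counts[k])) {
      ok <- FALSE
      for (try in seq_len(maxRetries)) {
        x <- stats::runif(1, -windowUm[1] / 2 + d / 2, windowUm[1] / 2 - d / 2)
        y <- stats::runif(1, -windowUm[2] / 2 + d / 2, windowUm[2] / 2 - d / 2)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2) >=
                (placed[, 3] + d) / 2 + minGapUm)) {
          placed <- rbind(placed, c(x, y, d)); ok <- TRUE; break
        }
      }
      if (!ok)
        stop("bead placement failed after ", maxRetries, " retries; placed ",
             nrow(placed), " of ", sum(counts), " beads")
    }
  }
  placed
}

#' Binary stripe grating phantom
#'
#' @param pitchUm stripe period (um)
#' @param orientationDeg stripe normal direction (0 = stripes vary along x)
#' @param duty bright-fraction of the period
#' @param windowUm scene window c(width, height) (um)
#' @param pixelScale scene um/px
#' @param channel channel carrying the grating
#' @return a [Scene-class]
#' @export
makeStripePhantom <- function(pitchUm, orientationDeg = 0, duty = 0.5,
                              windowUm = c(210, 210), pixelScale = 0.5,
                              channel = "CARS") {
  if (pitchUm <= 0) stop("pitchUm must be positive")
  if (pitchUm < 2 * pixelScale)
    stop("pitch ", pitchUm, " um is below two scene pixels (",
         2 * pixelScale, " um)")
  nc <- round(windowUm[1] / pixelScale)
  nr <- round(windowUm[2] / pixelScale)
  xs <- (seq_len(nc) - (nc + 1) / 2) * pixelScale
  ys <- (seq_len(nr) - (nr + 1) / 2) * pixelScale
  th <- orientationDeg * pi / 180
  U <- outer(ys * sin(th), xs * cos(th), "+")
  phase <- (U / pitchUm) %% 1
  img <- (phase < duty) + 0
  ch <- .emptyChannels(nr, nc)
  ch[[channel]] <- img
  .newScene(ch, pixelScale, "stripe",
            list(pitch = pitchUm, orientation = orientationDeg, duty = duty))
}

#' Smooth random tissue-like phantom
#'
#' Smoothed positive random blob fields per channel with configurable
#' inter-channel mixing (partial co-localization of lipid, collagen and
#' autofluorophore structures). With the identity mixing matrix the channels
#' are independent; an all-zero mixing matrix yields an all-zero scene.
#'
#' @param seed integer seed
#' @param windowUm scene window c(width, height) (um)
#' @param pixelScale scene um/px
#' @param blobSigmaUm correlation length of the blobs (um)
#' @param mixing 3 x 3 matrix mapping latent fields to (CARS, SHG, TPEF)
#' @return a [Scene-class]
#' @export
makeTissuePhantom <- function(seed = 1L, windowUm = c(210, 210),
                              pixelScale = 0.5, blobSigmaUm = 8,
                              mixing = diag(3)) {
  nc <- round(windowUm[1] / pixelScale)
  nr <- round(windowUm[2] / pixelScale)
  latent <- .withSeed(seed, 0L, function() {
    lapply(1:3, function(i) {
      f <- .gblur(matrix(stats::rnorm(nr * nc), nr, nc),
                  blobSigmaUm / pixelScale)
      (f - mean(f)) / stats::sd(f)
    })
  })
  chNames <- c("CARS", "SHG", "TPEF")
  ch <- stats::setNames(lapply(1:3, function(c) {
    m <- matrix(0, nr, nc)
    for (j in 1:3) m <- m + mixing[c, j] * latent[[j]]
    pmax(m, 0)
  }), chNames)
  .newScene(ch, pixelScale, "tissue",
            list(seed = seed, blobSigma = blobSigmaUm, mixing = mixing))
}

#' Flat (constant) scene
#'
#' @param level constant signal density
#' @param windowUm scene window (um)
#' @param pixelScale scene um/px
#' @return a [Scene-class]
#' @export
makeFlatScene <- function(level = 1, windowUm = c(210, 210), pixelScale = 1) {
  nc <- round(windowUm[1] / pixelScale)
  nr <- round(windowUm[2] / pixelScale)
  ch <- .emptyChannels(nr, nc)
  for (nm in names(ch)) ch[[nm]] <- matrix(level, nr, nc)
  .newScene(ch, pixelScale, "flat", list(level = level))
}

## blur a scene channel with the excitation spot kernel (sample-plane um)
.blurSceneChannel <- function(scene, channel, spotFwhmUm) {
  img <- sceneChannel(scene, channel)
  .gblur(img, spotFwhmUm / (2 * sqrt(2 * log(2))) / scene@pixelScale)
}

## scene coordinate (um) -> fractional pixel position
.scenePos <- function(scene, x, y) {
  list(row = (y - scene@origin[2]) / scene@pixelScale + 1,
       col = (x - scene@origin[1]) / scene@pixelScale + 1)
}

#' Acquire one raw proximal-end tile
#'
#' For each core i the spot-blurred scene is sampled at the
#' magnification-scaled core position plus the stage offset; the recorded
#' value is `t_i^p * s_i` (transmission `t_i`, channel excitation exponent
#' `p`). The tile is rendered by painting each core's value over its aperture
#' on a dark inter-core background; the core lattice itself is drawn shifted
#' by the accumulated incoupling drift (scan pattern drifting over the fiber
#' facet). Poisson shot noise at the configured photon scale plus Gaussian
#' read noise is applied per frame and averaged over `averages` frames.
#' Reproducible for fixed (seed, tileIndex).
#'
#' @param scene a [Scene-class]
#' @param map a [CoreMap-class]
#' @param meta an [AcquisitionMeta-class]
#' @param tileIndex 1-based tile index into `meta@stagePositions`
#' @param drift accumulated incoupling drift (um); default derives from
#'   `meta@driftPerTile` under the linear model
#' @param blurred optional precomputed spot-blurred scene channel
#' @return numeric ny x nx matrix (arbitrary detector units)
#' @export
acquireTile <- function(scene, map, meta, tileIndex = 1L, drift = NULL,
                        blurred = NULL) {
  validObject(meta)
  if (is.null(drift))
    drift <- .driftAt(meta, tileIndex)
  if (is.null(blurred))
    blurred <- .blurSceneChannel(scene, meta@channel, meta@spotFwhm)

  stage <- meta@stagePositions[tileIndex, ]
  ## only cores that can appear in the raster field contribute
  hwx <- meta@nx * meta@pixelScale / 2 + max(map@diameters) / 2 + abs(drift[1])
  hwy <- meta@ny * meta@pixelScale / 2 + max(map@diameters) / 2 + abs(drift[2])
  inField <- abs(map@centers[, 1]) <= hwx & abs(map@centers[, 2]) <= hwy
  if (any(!inField)) {
    map <- new("CoreMap", centers = map@centers[inField, , drop = FALSE],
               diameters = map@diameters[inField],
               transmissions = map@transmissions[inField],
               spec = map@spec, seed = map@seed)
  }
  samp <- cbind(map@centers[, 1] * meta@magnification + stage[1],
                map@centers[, 2] * meta@magnification + stage[2])
  d <- dim(blurred)
  xr <- scene@origin[1] + c(0, d[2] - 1) * scene@pixelScale
  yr <- scene@origin[2] + c(0, d[1] - 1) * scene@pixelScale
  if (nCores(map) > 0 &&
      (any(samp[, 1] < xr[1]) || any(samp[, 1] > xr[2]) ||
       any(samp[, 2] < yr[1]) || any(samp[, 2] > yr[2])))
    stop("scene does not cover the magnified field at stage position (",
         stage[1], ", ", stage[2], ") um")
  pos <- .scenePos(scene, samp[, 1], samp[, 2])
  s <- .bilinear(blurred, pos$row, pos$col)
  v <- map@transmissions^meta@excitationExponent * s

  rcw <- renderCoreWeights(map, meta@pixelScale, c(meta@nx, meta@ny),
                           magnification = 1, offset = drift)
  tile <- matrix(meta@background, meta@ny, meta@nx)
  inCore <- rcw$index > 0L
  tile[inCore] <- meta@background +
    v[rcw$index[inCore]] * rcw$weight[inCore]

  if (is.finite(meta@photonsPerUnit) || meta@readSigma > 0) {
    tile <- .withSeed(meta@seed, tileIndex, function() {
      acc <- matrix(0, meta@ny, meta@nx)
      n <- length(tile)
      for (a in seq_len(meta@averages)) {
        frame <- tile
        if (is.finite(meta@photonsPerUnit)) {
          lam <- pmax(tile, 0) * meta@photonsPerUnit
          frame <- matrix(stats::rpois(n, lam), meta@ny, meta@nx) /
            meta@photonsPerUnit
        }
        if (meta@readSigma > 0)
          frame <- frame + matrix(stats::rnorm(n, sd = meta@readSigma),
                                  meta@ny, meta@nx)
        acc <- acc + frame
      }
      acc / meta@averages
    })
  }
  tile
}

## accumulated drift before tile t
.driftAt <- function(meta, tileIndex) {
  if (meta@driftModel == "linear")
    return((tileIndex - 1) * meta@driftPerTile)
  .driftWalk(meta)[tileIndex, ]
}

## random-walk drift trace with the same expected total magnitude as linear
.driftWalk <- function(meta) {
  n <- nrow(meta@stagePositions)
  .withSeed(meta@seed, -1L, function() {
    step <- sqrt(sum(meta@driftPerTile^2))
    inc <- matrix(stats::rnorm(2 * (n - 1), sd = step), ncol = 2)
    rbind(c(0, 0), apply(inc, 2, cumsum))
  })
}

#' Acquire a full tile series with incoupling drift
#'
#' Generates the tiles of `meta@stagePositions` in order, accumulating
#' incoupling drift (`driftPerTile` per tile under the linear model, so the
#' default calibration of one core-to-core distance per 100 tiles gives a
#' total drift of ~4.69 um). The ground-truth drift trace is retained in the
#' returned stack for audit and testing.
#'
#' @inheritParams acquireTile
#' @return a [TileStack-class]
#' @export
acquireSeries <- function(scene, map, meta) {
  n <- nrow(meta@stagePositions)
  if (n == 0) stop("meta@stagePositions must be non-empty")
  blurred <- .blurSceneChannel(scene, meta@channel, meta@spotFwhm)
  trace <- if (meta@driftModel == "linear") {
    outer(seq_len(n) - 1, meta@driftPerTile)
  } else .driftWalk(meta)
  tilesList <- vector("list", n)
  for (t in seq_len(n)) {
    tilesList[[t]] <- tryCatch(
      acquireTile(scene, map, meta, t, drift = trace[t, ], blurred = blurred),
      error = function(e) stop("tile ", t, ": ", conditionMessage(e)))
  }
  new("TileStack", tiles = tilesList, meta = meta, coreMap = map,
      driftTrace = trace)
}

#' Regular grid of stage positions
#'
#' @param nxTiles,nyTiles grid size
#' @param shiftUm lateral shift between neighbouring tiles (um)
#' @param center centre the grid on (0, 0)
#' @return n x 2 matrix of stage positions, row-major tile order
#' @export
stageGrid <- function(nxTiles, nyTiles = nxTiles, shiftUm, center = TRUE) {
  xs <- (seq_len(nxTiles) - 1) * shiftUm
  ys <- (seq_len(nyTiles) - 1) * shiftUm
  if (center) { xs <- xs - mean(xs); ys <- ys - mean(ys) }
  cbind(x = rep(xs, times = nyTiles), y = rep(ys, each = nxTiles))
}
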