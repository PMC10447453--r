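#' Generate a fiber-bundle core map
#'
#' Places cores on an ideal hexagonal lattice at the specified spacing and
#' perturbs each centre by a spatially correlated displacement field
#' (Gaussian field with a correlation length of about two lattice spacings)
#' whose per-core RMS displacement equals that of a uniform draw from a disk
#' of radius `latticeJitterFrac * spacing`. Correlated disorder mimics the
#' quasi-hexagonal structure of drawn imaging fiber, where neighbouring cores
#' deform together: individual core positions wander by the jitter amplitude
#' while the measured mean core-to-core centre distance stays at the
#' specified spacing (independent per-core jitter would visibly shrink the
#' nearest-neighbour mean). Cores whose centres fall outside the imaging
#' circle are removed, per-core diameters are drawn uniformly within the
#' configured bounds, per-core transmissions from a log-normal distribution
#' of mean 1 and the configured coefficient of variation, and the configured
#' fraction of randomly chosen cores is set dead (transmission 0).
#' Bit-reproducible for a fixed seed.
#'
#' @param spec a [BundleSpec-class]
#' @param seed integer seed
#' @return a [CoreMap-class]
#' @examples
#' map <- generateBundle(BundleSpec(), seed = 1)
#' nCores(map)
#' @export
generateBundle <- function(spec, seed = 1L) {
  validObject(spec)
  s <- spec@meanCoreDistance
  R <- spec@imagingDiameter / 2
  rowStep <- s * sqrt(3) / 2
  nRows <- ceiling(R / rowStep) + 1L
  nColsHalf <- ceiling(R / s) + 1L
  rows <- seq(-nRows, nRows)
  centers <- do.call(rbind, lapply(rows, function(k) {
    xs <- seq(-nColsHalf, nColsHalf) * s + (k %% 2) * s / 2
    cbind(xs, k * rowStep)
  }))

  .withSeed(seed, 0L, function() {
    n0 <- nrow(centers)
    jf <- spec@latticeJitterFrac
    if (jf > 0) {
      ## smooth displacement field sampled on a lattice-pitch grid; per-core
      ## RMS displacement matched to a uniform disk of radius jf * s
      ## (per-component sd R/2)
      ext <- max(abs(centers)) + 3 * s
      ng <- max(8L, ceiling(2 * ext / s) + 1L)
      gx <- seq(-ext, ext, length.out = ng)
      field <- lapply(1:2, function(k) {
        f <- .gblur(matrix(stats::rnorm(ng * ng), ng, ng), 2)
        (f - mean(f)) / stats::sd(f) * (jf * s / 2)
      })
      gridPos <- function(v) (v + ext) / (2 * ext) * (ng - 1) + 1
      centers <- centers + cbind(
        .bilinear(field[[1]], gridPos(centers[, 2]), gridPos(centers[, 1])),
        .bilinear(field[[2]], gridPos(centers[, 2]), gridPos(centers[, 1])))
    }
    inside <- sqrt(rowSums(centers^2)) <= R
    centers <- centers[inside, , drop = FALSE]
    n <- nrow(centers)
    diameters <- stats::runif(n, spec@coreDiameterMin, spec@coreDiameterMax)
    cv <- spec@transmissionCV
    transmissions <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, n)
    nDead <- round(spec@deadCoreFrac * n)
    if (nDead > 0)
      transmissions[sample.int(n, nDead)] <- 0
    colnames(centers) <- c("x", "y")
    new("CoreMap", centers = centers, diameters = diameters,
        transmissions = transmissions, spec = spec, seed = as.integer(seed))
  })
}

#' Nearest-neighbour distance statistics of a core map
#'
#' Computes, for every core, the distance to its nearest neighbour, using a
#' cell-binning search (exact; each core is compared against cores in its
#' 3 x 3 cell neighbourhood with the cell size chosen large enough to contain
#' the nearest neighbour). The mean is reported to 0.01 um, matching the
#' convention of a measured average core-to-core centre distance.
#'
#' @param map a [CoreMap-class] with at least 2 cores
#' @return list with `mean`, `sd`, `min`, `max` of the per-core
#'   nearest-neighbour distances (um) and the raw `distances` vector
#' @export
nearestNeighborStats <- function(map) {
  n <- nCores(map)
  if (n < 2) stop("nearestNeighborStats needs at least 2 cores")
  d <- .nearestNeighborDistances(map@centers, cell = map@spec@meanCoreDistance)
  list(mean = .round(mean(d), 2), sd = stats::sd(d),
       min = min(d), max = max(d), distances = d)
}

## exact nearest-neighbour distances via cell binning; widens the search
## radius until every core has a neighbour within it
.nearestNeighborDistances <- function(centers, cell) {
  n <- nrow(centers)
  if (n <= 400) {                      # small maps: direct all-pairs
    D <- as.matrix(stats::dist(centers))
    diag(D) <- Inf
    return(unname(apply(D, 1, min)))
  }
  best <- rep(Inf, n)
  reach <- 1L
  repeat {
    h <- cell * reach
    cx <- floor((centers[, 1] - min(centers[, 1])) / h)
    cy <- floor((centers[, 2] - min(centers[, 2])) / h)
    key <- cx + cy * (max(cx) + 2)
    buckets <- split(seq_len(n), key)
    lookup <- new.env(hash = TRUE, size = length(buckets))
    for (k in names(buckets)) assign(k, buckets[[k]], envir = lookup)
    nx <- max(cx) + 2
    for (b in buckets) {
      kx <- cx[b[1]]; ky <- cy[b[1]]
      neigh <- integer(0)
      for (dx in -1:1) for (dy in -1:1) {
        k2 <- as.character((kx + dx) + (ky + dy) * nx)
        if (exists(k2, envir = lookup, inherits = FALSE))
          neigh <- c(neigh, get(k2, envir = lookup, inherits = FALSE))
      }
      P <- centers[neigh, , drop = FALSE]
      for (i in b) {
        dd <- (P[, 1] - centers[i, 1])^2 + (P[, 2] - centers[i, 2])^2
        dd[neigh == i] <- Inf
        best[i] <- sqrt(min(dd))
      }
    }
    if (all(is.finite(best)) && all(best <= h)) break
    reach <- reach * 2L
    best <- rep(Inf, n)
  }
  best
}

#' Rasterize core apertures to index and weight maps
#'
#' Maps every raster pixel falling inside a core's aperture to that core's
#' index, with an aperture weight (uniform disk by default, or a Gaussian of
#' FWHM equal to the core diameter). Where jittered cores overlap, the pixel
#' is assigned to the nearest centre (normalized by core radius) and a single
#' warning is emitted. Core positions and diameters are scaled by
#' `magnification` before rasterization; `offset` (um) translates the whole
#' lattice, which models incoupling drift of the scan pattern relative to the
#' fiber facet.
#'
#' @param map a [CoreMap-class]
#' @param pixelScaleUm um per raster pixel
#' @param imageSizePx integer pair c(nx, ny)
#' @param magnification scale factor applied to the core coordinates
#' @param aperture "disk" or "gaussian"
#' @param offset lattice translation (um), length 2
#' @param fieldCenter raster field centre in bundle coordinates (um)
#' @return list with `index` (integer matrix, 0 = no core) and `weight`
#'   (numeric matrix in [0, 1])
#' @export
renderCoreWeights <- function(map, pixelScaleUm, imageSizePx,
                              magnification = 1,
                              aperture = c("disk", "gaussian"),
                              offset = c(0, 0), fieldCenter = c(0, 0)) {
  aperture <- match.arg(aperture)
  if (pixelScaleUm <= 0) stop("pixelScaleUm must be positive")
  nx <- as.integer(imageSizePx[1]); ny <- as.integer(imageSizePx[2])
  index <- matrix(0L, ny, nx)
  weight <- matrix(0, ny, nx)
  n <- nCores(map)
  if (n == 0) return(list(index = index, weight = weight))

  ## raster pixel (i, j) centre in um: left/top edge at fieldCenter - extent/2
  left <- fieldCenter[1] - nx * pixelScaleUm / 2
  top  <- fieldCenter[2] - ny * pixelScaleUm / 2
  cx <- (map@centers[, 1] * magnification + offset[1] - left) / pixelScaleUm + 0.5
  cy <- (map@centers[, 2] * magnification + offset[2] - top) / pixelScaleUm + 0.5
  radPx <- map@diameters * magnification / 2 / pixelScaleUm

  ## vectorized rasterization: a fixed template window around every core,
  ## exact fractional distances, overlaps resolved nearest-centre by writing
  ## entries in decreasing-distance order (last write = closest centre wins)
  W <- ceiling(2 * max(radPx)) + 3L
  half <- (W - 1L) %/% 2L
  tmpl <- seq.int(-half, half + (W - 1L) %% 2L)
  baseJ <- round(cx); baseI <- round(cy)
  JJ <- outer(baseJ, rep(tmpl, times = W), "+")   # n x W^2
  II <- outer(baseI, rep(tmpl, each = W), "+")
  DX <- JJ - cx; DY <- II - cy
  DN <- sqrt(DX^2 + DY^2) / radPx
  keep <- DN <= 1 + 0.5 / radPx & JJ >= 1 & JJ <= nx & II >= 1 & II <= ny
  if (any(keep)) {
    coreId <- as.vector(row(JJ))[keep]
    pix <- (as.vector(JJ)[keep] - 1L) * ny + as.vector(II)[keep]
    dn <- as.vector(DN)[keep]
    ## disk aperture edges are antialiased over one pixel (subpixel coverage)
    w <- if (aperture == "disk") {
      pmin(1, pmax(0, (1 - dn) * radPx[coreId] + 0.5))
    } else {
      d <- dn * radPx[coreId]
      exp(-4 * log(2) * (d / (2 * radPx[coreId]))^2)
    }
    o <- order(dn, decreasing = TRUE)
    index[pix[o]] <- coreId[o]
    weight[pix[o]] <- w[o]
    nOverlap <- sum(duplicated(pix))
    if (nOverlap > 0)
      warning(nOverlap, " pixel(s) inside overlapping cores; ",
              "nearest centre wins")
  }
  list(index = index, weight = weight)
}

#' Write / read a core map as CSV plus JSON sidecar
#'
#' The CSV carries one row per core (`x_um`, `y_um`, `diameter_um`,
#' `transmission`); the JSON sidecar carries the generating [BundleSpec-class]
#' and seed so the map round-trips losslessly.
#'
#' @param map a [CoreMap-class]
#' @param csvPath output CSV path; the sidecar is written next to it as
#'   `<path>.json`
#' @return `writeCoreMap`: the CSV path, invisibly; `readCoreMap`: a
#'   [CoreMap-class]
#' @export
writeCoreMap <- function(map, csvPath) {
  df <- data.frame(x_um = map@centers[, 1], y_um = map@centers[, 2],
                   diameter_um = map@diameters,
                   transmission = map@transmissions)
  utils::write.csv(df, csvPath, row.names = FALSE)
  spec <- map@spec
  side <- list(
    spec = list(imagingDiameter = spec@imagingDiameter,
                meanCoreDistance = spec@meanCoreDistance,
                coreDiameterMin = spec@coreDiameterMin,
                coreDiameterMax = spec@coreDiameterMax,
                latticeJitterFrac = spec@latticeJitterFrac,
                transmissionCV = spec@transmissionCV,
                deadCoreFrac = spec@deadCoreFrac),
    seed = map@seed)
  jsonlite::write_json(side, paste0(csvPath, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}

#' @param csvPath path written by `writeCoreMap`
#' @rdname writeCoreMap
#' @export
readCoreMap <- function(csvPath) {
  df <- utils::read.csv(csvPath)
  side <- jsonlite::read_json(paste0(csvPath, ".json"), simplifyVector = TRUE)
  spec <- do.call(BundleSpec, as.list(side$spec))
  new("CoreMap",
      centers = cbind(x = df$x_um, y = df$y_um),
      diameters = df$diameter_um, transmissions = df$transmission,
      spec = spec, seed = as.integer(side$seed))
}
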