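## Quantitative evaluation: line profiles, modulation depth, resolved pitch,
## peak SNR, reconstruction fidelity, RGB compositing.

#' Averaged line profile over a rectangular ROI
#'
#' Means the intensities across the short axis of an axis-aligned rectangle
#' and returns them against position along the long axis, optionally min-max
#' normalized to [0, 1].
#'
#' @param image numeric matrix
#' @param roi integer vector c(row1, row2, col1, col2), inclusive, inside the
#'   image
#' @param pixelScaleUm um per pixel (for the position axis)
#' @param normalize min-max normalize the profile
#' @param along "auto" (long axis), "rows" or "cols": the profile direction
#' @return a [LineProfile-class]
#' @export
lineProfile <- function(image, roi, pixelScaleUm = 1, normalize = FALSE,
                        along = c("auto", "rows", "cols")) {
  along <- match.arg(along)
  roi <- as.integer(roi)
  if (length(roi) != 4L || roi[1] > roi[2] || roi[3] > roi[4] ||
      roi[1] < 1L || roi[3] < 1L || roi[2] > nrow(image) || roi[4] > ncol(image))
    stop("degenerate or out-of-image ROI")
  sub <- image[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  if (along == "auto")
    along <- if (ncol(sub) >= nrow(sub)) "cols" else "rows"
  prof <- if (along == "cols") colMeans(sub, na.rm = TRUE)
          else rowMeans(sub, na.rm = TRUE)
  if (anyNA(prof)) stop("ROI contains fully invalid lines")
  if (normalize) {
    rng <- range(prof)
    prof <- if (diff(rng) > 0) (prof - rng[1]) / diff(rng) else prof * 0
  }
  new("LineProfile", positions = (seq_along(prof) - 1) * pixelScaleUm,
      intensities = unname(prof), normalized = normalize)
}

#' Modulation depth of a profile
#'
#' Detects interior peak/valley/peak triplets in the profile (plateaus are
#' collapsed first) and returns the mean of
#' `(mean(flanking peaks) - valley) / (mean(flanking peaks) + valley)` over
#' all triplets: 1 for a full-contrast square wave, 0 for a featureless
#' profile. Computed on the profile values as given; feed a min-max
#' normalized profile (see [lineProfile()]) to make the result invariant to
#' affine intensity rescaling. Profile endpoints count as flanking extrema,
#' so a single valley between two boundary plateaus is detected.
#'
#' @param profile a [LineProfile-class] or numeric vector
#' @param smoothPts optional running-mean half-width (points) applied before
#'   extremum detection (0 = none)
#' @return modulation depth in [0, 1]
#' @export
modulationDepth <- function(profile, smoothPts = 0L) {
  y <- if (is(profile, "LineProfile")) profile@intensities else as.numeric(profile)
  y <- y[is.finite(y)]
  if (length(y) < 3) return(0)
  if (smoothPts > 0) {
    k <- 2L * as.integer(smoothPts) + 1L
    y <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
    y <- y[is.finite(y)]
    if (length(y) < 3) return(0)
  }
  if (diff(range(y)) == 0) return(0)
  ## collapse plateaus, locate extrema as sign changes of the difference;
  ## the profile endpoints join the extrema sequence (alternating by
  ## construction)
  r <- rle(y)$values
  if (length(r) < 3) return(0)
  d <- sign(diff(r))
  intExt <- which(d[-1] != d[-length(d)]) + 1L
  vals <- r[c(1L, intExt, length(r))]
  if (length(vals) < 3) return(0)
  mods <- c()
  for (k in 2:(length(vals) - 1)) {
    if (vals[k] < vals[k - 1] && vals[k] < vals[k + 1]) {
      pk <- mean(c(vals[k - 1], vals[k + 1]))
      vy <- vals[k]
      if (pk + vy > 0) mods <- c(mods, (pk - vy) / (pk + vy))
    }
  }
  if (length(mods) == 0) return(0)
  mean(mods)
}

#' Smallest resolved stripe pitch from a modulation sweep
#'
#' Given modulation depths measured on reconstructions of stripe phantoms
#' over a series of pitches spanning the resolution transition, returns the
#' smallest pitch at which the modulation reaches `threshold` (a
#' Rayleigh-like criterion; default 0.1), linearly interpolated between the
#' bracketing pitches.
#'
#' @param pitchesUm stripe pitches (um)
#' @param modulations modulation depth at each pitch
#' @param threshold resolution criterion on the modulation depth
#' @return smallest resolved pitch (um)
#' @export
smallestResolvedPitch <- function(pitchesUm, modulations, threshold = 0.1) {
  stopifnot(length(pitchesUm) == length(modulations))
  o <- order(pitchesUm)
  p <- pitchesUm[o]; m <- modulations[o]
  below <- which(m < threshold)
  if (length(below) == 0)
    stop("no transition in range: all pitches in [", min(p), ", ", max(p),
         "] um are resolved (modulation >= ", threshold, ")")
  i <- max(below)
  if (i == length(p))
    stop("no transition in range: largest pitch ", max(p),
         " um is unresolved (modulation ", signif(m[i], 3), " < ", threshold, ")")
  p[i] + (threshold - m[i]) * (p[i + 1] - p[i]) / (m[i + 1] - m[i])
}

#' Peak signal-to-noise ratio between two ROIs
#'
#' `(max of the smoothed signal ROI - mean of the background ROI) / (sd of
#' the background ROI)`. The signal ROI is smoothed with a small Gaussian
#' before taking the maximum so the peak is not itself a noise excursion.
#'
#' @param image numeric matrix
#' @param signalRoi,backgroundRoi integer vectors c(row1, row2, col1, col2);
#'   must be disjoint
#' @param smoothSigmaPx Gaussian smoothing sigma (px) applied to the signal
#'   ROI
#' @return peak SNR (dimensionless)
#' @export
peakSnr <- function(image, signalRoi, backgroundRoi, smoothSigmaPx = 1) {
  .roiRect <- function(r) list(rows = r[1]:r[2], cols = r[3]:r[4])
  s <- .roiRect(as.integer(signalRoi)); b <- .roiRect(as.integer(backgroundRoi))
  if (length(intersect(s$rows, b$rows)) > 0 &&
      length(intersect(s$cols, b$cols)) > 0)
    stop("signal and background ROIs must be disjoint")
  sig <- image[s$rows, s$cols, drop = FALSE]
  bg <- image[b$rows, b$cols, drop = FALSE]
  sdBg <- stats::sd(bg, na.rm = TRUE)
  if (!is.finite(sdBg) || sdBg == 0)
    stop("background ROI has zero variance (noise-free input?)")
  sigS <- if (smoothSigmaPx > 0) .gblur(sig, smoothSigmaPx) else sig
  (max(sigS, na.rm = TRUE) - mean(bg, na.rm = TRUE)) / sdBg
}

#' Reconstruction fidelity against a ground-truth scene
#'
#' Resamples the ground truth onto the reconstruction grid, fits a single
#' intensity gain (reconstructed images carry arbitrary units), and reports
#' the normalized RMSE (RMSE over the truth's intensity range, or its mean
#' for a flat truth) plus a windowed structural-similarity score (Gaussian
#' windows, standard stabilizing constants) over valid pixels.
#'
#' @param recon a [Mosaic-class], or a numeric matrix (then `reconScale` and
#'   `reconOrigin` give its grid)
#' @param truth a [Scene-class] plus `channel`, or a numeric matrix on the
#'   same grid as `recon`
#' @param channel scene channel to compare against
#' @param reconScale,reconOrigin grid of a bare-matrix `recon`
#' @return list with `nrmse` and `ssim`
#' @export
fidelity <- function(recon, truth, channel = "CARS",
                     reconScale = NULL, reconOrigin = NULL) {
  if (is(recon, "Mosaic")) {
    r <- recon@image; reconScale <- recon@pixelScale; reconOrigin <- recon@origin
  } else r <- recon
  if (is(truth, "Scene")) {
    tch <- sceneChannel(truth, channel)
    nr <- nrow(r); nc <- ncol(r)
    X <- reconOrigin[1] + (seq_len(nc) - 1) * reconScale
    Y <- reconOrigin[2] + (seq_len(nr) - 1) * reconScale
    pos <- .scenePos(truth, rep(X, each = nr), rep(Y, times = nc))
    tt <- matrix(.bilinear(tch, pos$row, pos$col), nr, nc)
  } else tt <- truth
  ok <- is.finite(r) & is.finite(tt)
  if (!any(ok)) stop("no overlapping valid pixels")
  a <- r; a[!ok] <- NA; b <- tt; b[!ok] <- NA
  ## single least-squares gain on the reconstruction
  g <- sum(a * b, na.rm = TRUE) / sum(a * a, na.rm = TRUE)
  if (!is.finite(g) || g == 0) g <- 1
  a <- a * g
  rmse <- sqrt(mean((a - b)^2, na.rm = TRUE))
  rngT <- diff(range(b, na.rm = TRUE))
  ## an (effectively) flat truth has no intensity range; normalize by its mean
  flat <- rngT <= 1e-8 * max(abs(b), na.rm = TRUE)
  nrmse <- rmse / if (flat) mean(abs(b), na.rm = TRUE) else rngT
  list(nrmse = nrmse, ssim = .ssim(a, b, ok))
}

## mean windowed SSIM (Gaussian window sigma 1.5 px, K1=0.01, K2=0.03)
.ssim <- function(a, b, ok) {
  a[!ok] <- 0; b[!ok] <- 0
  w <- ok + 0
  L <- max(diff(range(a[ok])), diff(range(b[ok])), .Machine$double.eps)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  g <- function(m) .gblur(m, 1.5)
  W <- pmax(g(w), 1e-9)
  muA <- g(a) / W; muB <- g(b) / W
  sAA <- g(a * a) / W - muA^2
  sBB <- g(b * b) / W - muB^2
  sAB <- g(a * b) / W - muA * muB
  s <- ((2 * muA * muB + C1) * (2 * sAB + C2)) /
       ((muA^2 + muB^2 + C1) * (sAA + sBB + C2))
  mean(s[ok])
}

#' Composite three channels to an 8-bit RGB image
#'
#' Fixed colour coding: CARS maps to red, SHG to blue, TPEF to green. Each
#' channel is scaled between its lower and upper intensity percentiles
#' (default 1 and 99, so at most ~1% of pixels saturate per channel); the
#' scaling bounds are attached as the `"scaling"` attribute for the run
#' manifest.
#'
#' @param cars,shg,tpef co-registered numeric matrices (NA allowed; rendered
#'   black); pass a zero matrix for an absent channel
#' @param probs length-2 percentile bounds for the scaling
#' @return h x w x 3 array in [0, 1] with attribute `"scaling"`
#' @export
composeRgb <- function(cars, shg, tpef, probs = c(0.01, 0.99)) {
  chans <- list(CARS = cars, TPEF = tpef, SHG = shg)  # R, G, B order
  d <- dim(chans[[1]])
  for (m in chans) if (!identical(dim(m), d))
    stop("channel dimensions differ")
  scaling <- list()
  out <- array(0, c(d[1], d[2], 3))
  for (k in 1:3) {
    m <- chans[[k]]
    v <- m[is.finite(m)]
    if (length(v) == 0 || diff(range(v)) == 0) {
      scaling[[names(chans)[k]]] <- c(0, 1)
      next
    }
    q <- stats::quantile(v, probs, names = FALSE)
    if (q[2] <= q[1]) q[2] <- q[1] + .Machine$double.eps
    s <- (m - q[1]) / (q[2] - q[1])
    s[!is.finite(s)] <- 0
    out[, , k] <- pmin(pmax(s, 0), 1)
    scaling[[names(chans)[k]]] <- q
  }
  attr(out, "scaling") <- scaling
  out
}

#' Phase-averaged stripe contrast at a known pitch
#'
#' Folds an averaged line profile modulo a known stripe pitch and measures
#' the modulation depth of the folded (phase-averaged) period. Structure at
#' the stripe frequency survives the folding while aliased patterns and
#' residual lattice structure, whose frequencies differ from the stripe
#' frequency, average out -- so this is the appropriate transfer measure for
#' resolution sweeps where the imaged pitch is known. Returns
#' `(max - min) / (max + min)` of the folded profile.
#'
#' @param image numeric matrix (reconstruction of a stripe phantom)
#' @param pitchUm stripe pitch (um)
#' @param pixelScaleUm um per image pixel
#' @param roi optional ROI c(row1, row2, col1, col2); default central 70%
#' @param along profile direction across the stripes ("cols" for stripes
#'   varying along x)
#' @param nBins phase bins per period
#' @return contrast in [0, 1]
#' @export
stripeContrast <- function(image, pitchUm, pixelScaleUm, roi = NULL,
                           along = "cols", nBins = 12L) {
  d <- dim(image)
  if (is.null(roi))
    roi <- c(max(1, round(d[1] * 0.15)), min(d[1], round(d[1] * 0.85)),
             max(1, round(d[2] * 0.15)), min(d[2], round(d[2] * 0.85)))
  pr <- lineProfile(image, roi, pixelScaleUm, normalize = FALSE, along = along)
  pos <- pr@positions
  y <- pr@intensities
  if (diff(range(pos)) < 2 * pitchUm)
    stop("ROI spans fewer than two stripe periods")
  phase <- (pos / pitchUm) %% 1
  bins <- pmin(floor(phase * nBins) + 1L, nBins)
  folded <- tapply(y, bins, mean)
  if (any(is.na(folded))) return(0)
  pk <- max(folded); vy <- min(folded)
  if (pk + vy <= 0) return(0)
  max(0, (pk - vy) / (pk + vy))
}
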