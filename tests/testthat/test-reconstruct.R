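test_that("phase-correlation alignment recovers known translations", {
  tex <- fxTexture(96)

  ## single tile: identity
  one <- fxStackOf(list(tex))
  a1 <- alignStack(one)
  expect_equal(a1$offsets, matrix(0, 1, 2), ignore_attr = TRUE)
  expect_identical(tiles(a1$stack)[[1]], tex)

  ## circular shift by exactly (+3, -2) px: offset (-3, +2) recovered exactly
  shifted <- tex[c(94:96, 1:93), c(3:96, 1:2)]
  st <- fxStackOf(list(tex, shifted))
  al <- alignStack(st)
  expect_equal(unname(al$offsets[2, ]), c(-3, 2), tolerance = 1e-8)

  ## subpixel shift recovered to the upsampling resolution
  fshift <- function(x, dy, dx) {
    n1 <- nrow(x); n2 <- ncol(x)
    f1 <- c(0:floor(n1 / 2), -((ceiling(n1 / 2) - 1):1))
    f2 <- c(0:floor(n2 / 2), -((ceiling(n2 / 2) - 1):1))
    P <- exp(-2i * pi * outer(f1 * dy / n1, rep(0, n2), "+")) *
      exp(-2i * pi * outer(rep(0, n1), f2 * dx / n2, "+"))
    Re(fft(fft(x) * P, inverse = TRUE)) / (n1 * n2)
  }
  sub <- fshift(tex, 1.4, -0.6)
  alSub <- alignStack(fxStackOf(list(tex, sub)), PipelineConfig(alignUpsample = 20L))
  expect_equal(unname(alSub$offsets[2, ]), c(-1.4, 0.6), tolerance = 0.06)

  ## featureless tile falls below the correlation threshold and is flagged
  flat <- matrix(1, 96, 96)
  expect_warning(
    alF <- alignStack(fxStackOf(list(tex, flat)),
                      PipelineConfig(alignThreshold = 0.2)),
    "below the correlation threshold")
  expect_true(alF$flagged[2])
  expect_equal(unname(alF$offsets[2, ]), c(0, 0))
})

test_that("simulated incoupling drift is recovered within 0.5 px RMS", {
  map <- fxMap()
  scene <- fxFlatScene()
  meta <- fxMetaNoisy(matrix(0, 30, 2), driftPerTile = c(4.69 / 100, 2 / 100),
                      nx = 128L, ny = 128L)
  st <- acquireSeries(scene, map, meta)
  al <- alignStack(st, PipelineConfig())
  truthPx <- driftTrace(st) / meta@pixelScale    # (x, y) um -> px
  err <- cbind(al$offsets[, "dy"] + truthPx[, 2],
               al$offsets[, "dx"] + truthPx[, 1])
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("downscaling reaches the target core sampling and preserves flux", {
  ## spacing 46 px with target 4.6 px: scale factor 0.1
  big <- matrix(rlnorm(460 * 460), 460, 460)
  st <- fxStackOf(list(big))
  ds <- downscaleStack(st, spacingPx = 46, PipelineConfig())
  expect_equal(dim(tiles(ds)[[1]]), c(46, 46))
  expect_equal(mean(tiles(ds)[[1]]), mean(big), tolerance = 1e-12)
  expect_equal(pixelScale(ds), 10, tolerance = 1e-9)

  ## constant tile stays constant
  cst <- fxStackOf(list(matrix(5, 100, 100)))
  dc <- downscaleStack(cst, 9.2, PipelineConfig())
  expect_true(all(abs(tiles(dc)[[1]] - 5) < 1e-12))

  ## already at target: no-op with warning
  expect_warning(same <- downscaleStack(st, spacingPx = 4.0), "skipped")
  expect_identical(tiles(same)[[1]], big)
  expect_error(downscaleStack(st, spacingPx = -1), "positive")

  ## post-rescale core spacing is 4.6 px within 5% (lattice fixture)
  map <- fxMap()
  tile <- acquireTile(fxFlatScene(), map, fxMetaClean(), 1L)
  sp <- estimateCoreSpacing(tile)$spacing_px
  dsL <- downscaleStack(fxStackOf(list(tile), 0.55), sp, PipelineConfig())
  spNew <- estimateCoreSpacing(tiles(dsL)[[1]])$spacing_px
  expect_equal(spNew, 4.6, tolerance = 0.05)
})

test_that("median projection estimates per-pixel efficiency robustly", {
  m1 <- matrix(1, 4, 4); m2 <- matrix(2, 4, 4); m3 <- matrix(3, 4, 4)
  st <- fxStackOf(list(m1, m2, m3))
  expect_equal(efficiencyValues(medianProjection(st)), m2)
  expect_equal(efficiencyValues(medianProjection(fxStackOf(list(m2, m2)))), m2)

  ## running median: capacity eviction and outlier robustness
  buf <- RunningMedianBuffer(3L, 1)
  for (i in 1:3) buf <- updateRunningMedian(buf, m2)
  expect_equal(efficiencyValues(medianProjection(buf)), m2)
  buf100 <- RunningMedianBuffer(100L, 1)
  for (i in 1:100) buf100 <- updateRunningMedian(buf100, m1)
  buf100 <- updateRunningMedian(buf100, 100 * m1)
  expect_equal(efficiencyValues(medianProjection(buf100)), m1)

  ## slow gain drift: map tracks the new gain within 2% after 50 frames
  pattern <- matrix(rlnorm(64, sdlog = 0.3), 8, 8)
  buf <- RunningMedianBuffer(100L, 1)
  gain <- function(t) if (t < 50) 1 else 1.5
  for (t in 1:150) buf <- updateRunningMedian(buf, gain(t) * pattern)
  mp <- efficiencyValues(medianProjection(buf))
  expect_equal(mp, 1.5 * pattern, tolerance = 0.02)

  expect_error(updateRunningMedian(buf, matrix(1, 3, 3)), "do not match")
  expect_error(medianProjection(RunningMedianBuffer(5L, 1)), "empty")
})

test_that("flat-field division floors weak pixels instead of exploding", {
  map <- matrix(rlnorm(400), 20, 20)
  map[1:3, 1] <- 0                       # dead pixels
  eff <- new("EfficiencyMap", values = map, frames = 5L, pixelScale = 1)
  k <- 3.7
  st <- fxStackOf(list(k * map))
  out <- tiles(normalizeStack(st, eff, PipelineConfig()))[[1]]
  valid <- is.finite(out)
  expect_true(all(abs(out[valid] - k) < 1e-9))
  ## dead pixels masked, never infinite
  expect_true(all(is.na(out[1:3, 1])))
  expect_false(any(is.infinite(out)))

  zero <- new("EfficiencyMap", values = matrix(0, 20, 20), frames = 1L,
              pixelScale = 1)
  expect_error(normalizeStack(st, zero, PipelineConfig()), "all zero")
  small <- new("EfficiencyMap", values = matrix(1, 4, 4), frames = 1L,
               pixelScale = 1)
  expect_error(normalizeStack(st, small, PipelineConfig()), "do not match")

  ## simulated flat scene with heterogeneous gains, no noise: constant
  bundle <- fxMap()
  meta <- fxMetaClean(stageGrid(2, 2, 15), nx = 128L, ny = 128L)
  stSim <- acquireSeries(fxFlatScene(), bundle, meta)
  ds <- downscaleStack(stSim, NULL, PipelineConfig())
  nrm <- normalizeStack(ds, medianProjection(ds), PipelineConfig())
  tile <- tiles(nrm)[[1]]
  v <- tile[is.finite(tile)]
  expect_lt(sd(v) / mean(v), 0.01)
})

test_that("stitching blends tiles exactly and reproduces mosaic geometry", {
  cfg <- PipelineConfig(magnification = 1)
  c7 <- matrix(7, 40, 40)

  ## two constant tiles, 50% overlap: constant mosaic, no seam
  mos <- stitchMosaic(list(c7, c7), rbind(c(0, 0), c(20, 0)), 1, cfg)
  img <- mosaicImage(mos)
  expect_lt(max(abs(img[is.finite(img)] - 7)), 1e-9)
  expect_true(all(weightMap(mos)[is.finite(img)] > 0))

  ## blend weights sum to 1 after normalization: blending arbitrary equal
  ## tiles reproduces them exactly in the overlap
  tex <- fxTexture(40)
  mos2 <- stitchMosaic(list(tex, tex), rbind(c(0, 0), c(0, 0)), 1, cfg)
  expect_equal(mosaicImage(mos2), tex, tolerance = 1e-9, ignore_attr = TRUE)

  ## 12 x 12 grid at 190 um shift with 207 um tiles: extent 2297 um per axis
  cfgM <- PipelineConfig(magnification = 1.17)
  px <- 207 / 69 / 1.17                  # facet um/px so sample tile is 207 um
  tiles144 <- replicate(144, matrix(1, 69, 69), simplify = FALSE)
  mos3 <- suppressWarnings(   # outermost half-pixel ring is uncovered
    stitchMosaic(tiles144, stageGrid(12, 12, 190), px, cfgM))
  extent <- dim(mosaicImage(mos3)) * pixelScale(mos3)
  expect_equal(extent[1], 11 * 190 + 207, tolerance = 0.005)
  expect_equal(extent[2], 11 * 190 + 207, tolerance = 0.005)

  ## disjoint tiles leave an undefined gap with a warning
  expect_warning(
    gap <- stitchMosaic(list(c7, c7), rbind(c(0, 0), c(100, 0)), 1, cfg),
    "not covered")
  expect_true(anyNA(mosaicImage(gap)))

  expect_error(stitchMosaic(list(c7), rbind(c(0, 0), c(1, 1)), 1, cfg),
               "differ")
})

test_that("the spectral bandpass is linear, mean-preserving and selective", {
  n <- 128
  xs <- (seq_len(n) - 1)
  spacingUm <- 5.49
  smallCut <- 1.5 * spacingUm
  ## core-lattice period: attenuated by >= 20 dB
  lattice <- outer(rep(1, n), sin(2 * pi * xs * 1 / spacingUm)) # 1 um/px grid
  out <- fftBandpass(lattice, 1, smallCut, 100)
  expect_lt(sd(out) / sd(lattice), 0.1)
  ## 50 um period inside the band: preserved within 10%
  slow <- outer(rep(1, n), sin(2 * pi * xs / 50))
  outS <- fftBandpass(slow, 1, smallCut, 100)
  expect_equal(sd(outS) / sd(slow), 1, tolerance = 0.1)

  ## linear operator, and DC retention preserves the mean
  a <- fxTexture(64, seed = 1); b <- fxTexture(64, seed = 2)
  f <- function(x) fftBandpass(x, 1, 4, 40)
  expect_equal(f(a + b), f(a) + f(b), tolerance = 1e-9)
  withMean <- a + 5
  expect_equal(mean(f(withMean)), mean(withMean), tolerance = 0.01 * 5)

  expect_error(fftBandpass(a, 1, 10, 5), "must be <")
})

test_that("shifted superposition fills inter-core space", {
  tex <- fxTexture(48)
  ## single frame: identity up to the grid upsampling
  one <- superimposeShifted(list(tex), matrix(0, 1, 2), upsample = 1L,
                            pixelScaleUm = 1)
  expect_equal(mosaicImage(one), tex, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(superimposeShifted(list(), matrix(0, 0, 2)), "no tiles")

  ## sub-core shifts reconstruct scene structure between cores: a grating
  ## below the single-shot limit keeps contrast in the superposition that
  ## the honeycomb-free (bandpassed) single shot loses
  map <- fxUniformMap()
  pitch <- 6
  scene <- makeStripePhantom(pitch, 0, 0.5, c(240, 240), pixelScale = 0.5)
  shifts <- stageGrid(10, 10, 1)
  meta <- fxMetaNoisy(shifts, nx = 96L, ny = 96L)
  st <- acquireSeries(scene, map, meta)
  sp <- estimateCoreSpacing(tiles(st)[[1]], 0.55)$spacing_px
  cfg <- PipelineConfig()
  ds <- downscaleStack(st, sp, cfg)
  nrm <- normalizeStack(ds, medianProjection(ds), cfg)
  scl <- pixelScale(nrm) * cfg@magnification
  spacingSampleUm <- sp * 0.55 * cfg@magnification
  singleBp <- fftBandpass(tiles(nrm)[[1]], scl, 1.5 * spacingSampleUm,
                          96 * 0.55 * cfg@magnification)
  sup <- superimposeShifted(tiles(nrm), shifts, upsample = 3L,
                            pixelScaleUm = pixelScale(nrm),
                            magnification = cfg@magnification)
  cSingle <- stripeContrast(singleBp, pitch, scl)
  cSup <- stripeContrast(mosaicImage(sup), pitch, pixelScale(sup))
  expect_gt(cSup, 2 * cSingle)
  expect_gt(cSup, 0.05)
})

test_that("the pipeline runs its stages in the published order", {
  map <- fxMap()
  scene <- fxFlatScene()
  ## strong drift (~1 px per tile) so that skipping alignment visibly hurts
  meta <- fxMetaNoisy(stageGrid(3, 3, 20), driftPerTile = c(0.5, 0.2),
                      nx = 128L, ny = 128L)
  st <- acquireSeries(scene, map, meta)
  res <- suppressWarnings(runPipeline(st, PipelineConfig(), intermediates = TRUE))

  expect_s4_class(res$mosaic, "Mosaic")
  expect_named(res$manifest$stages,
               c("align", "downscale", "medianProjection", "normalize",
                 "stitch", "bandpass"))
  expect_equal(nrow(res$intermediates$offsets), 9)

  ## flat scene end to end: mosaic constant within 3% RMS over the interior
  img <- mosaicImage(res$mosaic)
  d <- dim(img)
  ctr <- img[round(d[1] * 0.3):round(d[1] * 0.7),
             round(d[2] * 0.3):round(d[2] * 0.7)]
  v <- ctr[is.finite(ctr)]
  expect_lt(sd(v) / mean(v), 0.03)

  ## normalizing before aligning degrades the flat-field residual
  cfg <- PipelineConfig()
  dsRaw <- downscaleStack(st, NULL, cfg)
  nrmFirst <- normalizeStack(dsRaw, medianProjection(dsRaw), cfg)
  alLater <- suppressWarnings(alignStack(nrmFirst, cfg))
  rmsOf <- function(stk) {
    x <- tiles(stk)[[5]]; v <- x[is.finite(x)]; sd(v) / mean(v)
  }
  alFirst <- alignStack(st, cfg)
  dsA <- downscaleStack(alFirst$stack, NULL, cfg)
  nrmProper <- normalizeStack(dsA, medianProjection(dsA), cfg)
  expect_lt(rmsOf(nrmProper), rmsOf(alLater$stack))

  ## stage errors are labelled with the stage name
  bad <- st
  bad@tiles <- lapply(tiles(st), function(t) t * 0)
  expect_error(suppressWarnings(runPipeline(bad, PipelineConfig())), "stage")
})

test_that("multi-channel pipelines composite to the fixed colour coding", {
  map <- fxUniformMap()
  scene <- makeTissuePhantom(3L, c(260, 260))
  stacks <- lapply(c(CARS = "CARS", TPEF = "TPEF"), function(ch)
    acquireSeries(scene, map,
                  fxMetaNoisy(stageGrid(2, 2, 15), channel = ch,
                              nx = 96L, ny = 96L)))
  res <- suppressWarnings(runPipeline(stacks, PipelineConfig()))
  expect_named(res$mosaics, c("CARS", "TPEF"))
  expect_equal(dim(res$composite)[3], 3)
  ## CARS drives red (slot 1), TPEF green (slot 2); SHG absent -> blue empty
  expect_true(all(res$composite[, , 3] == 0))
})
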