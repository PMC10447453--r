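test_that("bead phantoms place the requested disks with correct total area", {
  sc <- makeBeadPhantom(8, 20, c(210, 210), minGapUm = 0, seed = 2L)
  img <- sceneChannel(sc, "CARS")
  bg <- sc@params$background
  ## antialiased coverage integrates to the analytic disk area within 1%
  area <- sum((img - bg) / (1 - bg)) * sc@pixelScale^2
  expect_equal(area, 20 * pi * 16, tolerance = 0.01)
  expect_equal(nrow(sc@params$centers), 20)
  expect_true(all(sceneChannel(sc, "SHG") == 0))

  ## zero-count request: background only
  sc0 <- makeBeadPhantom(3, 0, c(50, 50))
  expect_true(all(sceneChannel(sc0, "CARS") == sc0@params$background))

  ## impossible request reports the achieved count
  expect_error(makeBeadPhantom(50, 100, c(110, 110), minGapUm = 5),
               "placed \\d+ of 100")

  ## reproducible by seed
  expect_identical(sceneChannel(makeBeadPhantom(c(3, 6), c(5, 5), seed = 4L), "CARS"),
                   sceneChannel(makeBeadPhantom(c(3, 6), c(5, 5), seed = 4L), "CARS"))

  ## explicit centres are honoured exactly
  scp <- makeBeadPhantom(8, centers = matrix(c(-4, 0, 4, 0), 2, 2, byrow = TRUE),
                         windowUm = c(60, 60))
  expect_equal(scp@params$centers, matrix(c(-4, 0, 4, 0), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("stripe phantoms have the requested pitch, duty and symmetry", {
  sc <- makeStripePhantom(10.6, 0, 0.5, c(212, 212), pixelScale = 0.5)
  img <- sceneChannel(sc, "CARS")
  expect_equal(mean(img), 0.5, tolerance = 0.02)
  expect_true(all(img %in% c(0, 1)))

  ## 90-degree rotation is the transpose
  sc90 <- makeStripePhantom(10.6, 90, 0.5, c(212, 212), pixelScale = 0.5)
  expect_equal(sceneChannel(sc90, "CARS"), t(img))

  ## discrete spectrum peaks at 1/pitch
  row <- img[1, ]
  sp <- Mod(fft(row - mean(row)))[2:(length(row) / 2)]
  kPeak <- which.max(sp) + 1L          # 1-based bin, bin k = k-1 cycles
  cyclesExpected <- length(row) * 0.5 / 10.6
  expect_equal(kPeak - 1L, round(cyclesExpected), tolerance = 0)

  expect_error(makeStripePhantom(0.5, pixelScale = 0.5), "below two scene pixels")
})

test_that("tissue phantoms are reproducible with controlled co-localization", {
  a <- makeTissuePhantom(5L, c(100, 100))
  b <- makeTissuePhantom(5L, c(100, 100))
  expect_identical(a@channels, b@channels)
  expect_true(all(vapply(a@channels, min, numeric(1)) >= 0))

  ## identity mixing: channels uncorrelated within sampling error
  cors <- cor(cbind(as.vector(sceneChannel(a, "CARS")),
                    as.vector(sceneChannel(a, "SHG")),
                    as.vector(sceneChannel(a, "TPEF"))))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.25)

  ## strong mixing raises the correlation well above the independent case
  mixed <- makeTissuePhantom(5L, c(100, 100),
                             mixing = matrix(c(1, 0.9, 0, 0.9, 1, 0, 0, 0, 1),
                                             3, 3, byrow = TRUE))
  rMixed <- cor(as.vector(sceneChannel(mixed, "CARS")),
                as.vector(sceneChannel(mixed, "SHG")))
  expect_gt(rMixed, 0.8)

  ## all-zero mixing -> all-zero scene
  z <- makeTissuePhantom(5L, c(100, 100), mixing = matrix(0, 3, 3))
  expect_true(all(vapply(z@channels, max, numeric(1)) == 0))
})

test_that("noise-free acquisition paints t^p-weighted samples over apertures", {
  map <- fxUniformMap()          # CV 0, no dead cores
  scene <- fxFlatScene()
  meta <- fxMetaClean()
  tile <- acquireTile(scene, map, meta, 1L)

  rcw <- renderCoreWeights(map, meta@pixelScale, c(meta@nx, meta@ny))
  full <- rcw$weight == 1
  ## flat scene + uniform transmissions: all core interiors equal
  vals <- tile[full]
  expect_lt(diff(range(vals)), 1e-9)
  ## inter-core pixels at the dark background
  expect_true(all(tile[rcw$index == 0L] == meta@background))

  ## acquisition is deterministic and linear in the scene
  expect_identical(acquireTile(scene, map, meta, 1L), tile)
  sc2 <- makeFlatScene(2, c(320, 320), 1)
  tile2 <- acquireTile(sc2, map, meta, 1L)
  expect_equal(tile2[full] - meta@background,
               2 * (tile[full] - meta@background), tolerance = 1e-9)

  ## varying transmissions, p = 2: core values proportional to t^2
  mapV <- fxMap()
  metaP2 <- fxMetaClean(channel = "TPEF")   # exponent 2
  tileV <- acquireTile(scene, mapV, metaP2, 1L)
  rcwV <- renderCoreWeights(mapV, meta@pixelScale, c(meta@nx, meta@ny))
  fullV <- rcwV$weight == 1
  idx <- rcwV$index[fullV]
  expect_equal(tileV[fullV] - metaP2@background,
               coreTransmissions(mapV)[idx]^2, tolerance = 1e-9)

  ## dead cores yield exactly background
  dead <- which(coreTransmissions(mapV) == 0)
  expect_gt(length(dead), 0)
  deadPx <- rcwV$index %in% dead & rcwV$weight > 0
  expect_true(all(tileV[deadPx] == metaP2@background))
})

test_that("per-core sampling agrees with direct numerical integration", {
  ## independent oracle: s_i = sum over scene pixels of scene * Gaussian spot
  map <- fxUniformMap()
  meta <- fxMetaClean(spotFwhm = 3.3)
  scene <- makeStripePhantom(21, 0, 0.5, c(320, 320), pixelScale = 0.5)
  tile <- acquireTile(scene, map, meta, 1L)

  rcw <- renderCoreWeights(map, meta@pixelScale, c(meta@nx, meta@ny))
  img <- sceneChannel(scene, "CARS")
  ps <- pixelScale(scene)
  d <- dim(img)
  xs <- scene@origin[1] + (seq_len(d[2]) - 1) * ps
  ys <- scene@origin[2] + (seq_len(d[1]) - 1) * ps
  sg <- 3.3 / (2 * sqrt(2 * log(2)))
  centers <- coreCenters(map)
  n <- 40L                                  # subset of cores
  set.seed(1)
  pick <- sample(nCores(map), n)
  pair <- vapply(pick, function(i) {
    cx <- centers[i, 1] * meta@magnification
    cy <- centers[i, 2] * meta@magnification
    wx <- dnorm(xs, cx, sg); wy <- dnorm(ys, cy, sg)
    sOracle <- sum(outer(wy, wx) * img) / sum(outer(wy, wx))
    full <- rcw$index == i & rcw$weight == 1
    c(mean(tile[full]) - meta@background, sOracle)
  }, numeric(2))
  expect_equal(pair[1, ], pair[2, ], tolerance = 0.02)
})

test_that("tile series accumulate the configured incoupling drift", {
  map <- fxUniformMap()
  scene <- fxFlatScene()

  ## default calibration: one core distance over 100 tiles
  meta <- fxMetaNoisy(matrix(0, 100, 2), driftPerTile = c(4.69 / 100, 0),
                      nx = 64L, ny = 64L)
  st <- acquireSeries(scene, map, meta)
  total <- driftTrace(st)[100, ]
  expect_equal(sqrt(sum(total^2)), 4.69 * 99 / 100, tolerance = 1e-9)

  ## zero drift, identical positions, no noise: identical tiles
  meta0 <- fxMetaClean(matrix(0, 4, 2), nx = 64L, ny = 64L)
  st0 <- acquireSeries(scene, map, meta0)
  expect_identical(tiles(st0)[[1]], tiles(st0)[[4]])

  ## a 10 x 10 grid at 1 um steps spans 9 x 9 um
  g <- stageGrid(10, 10, 1)
  expect_equal(max(g[, 1]) - min(g[, 1]), 9)
  expect_equal(max(g[, 2]) - min(g[, 2]), 9)
  expect_equal(nrow(g), 100)

  ## reproducibility tile-by-tile: series tile t equals standalone tile t
  t3 <- acquireTile(scene, map, meta, 3L, drift = driftTrace(st)[3, ])
  expect_identical(tiles(st)[[3]], t3)

  ## scene coverage violation names the stage position
  tiny <- makeFlatScene(1, c(30, 30), 1)
  expect_error(acquireSeries(tiny, map, meta0), "does not cover")
})
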