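test_that("line profiles average perpendicular to the ROI's long axis", {
  ## constant image: flat profile
  pf <- lineProfile(matrix(4, 20, 50), c(5, 15, 1, 50), pixelScaleUm = 2)
  expect_true(all(pf@intensities == 4))
  expect_equal(diff(pf@positions), rep(2, 49))

  ## stripes: square-wave profile of matching pitch
  img <- matrix(rep(rep(c(1, 0), each = 5), length.out = 60 * 40),
                40, 60, byrow = TRUE)
  pr <- lineProfile(img, c(1, 40, 1, 60))
  expect_equal(pr@intensities, rep(rep(c(1, 0), each = 5), length.out = 60))

  ## simulated 8 um bead pair: maxima separated by the centre distance
  sc <- makeBeadPhantom(8, centers = matrix(c(-4, 0, 4, 0), 2, 2, byrow = TRUE),
                        windowUm = c(60, 60), pixelScale = 0.5)
  img8 <- sceneChannel(sc, "CARS")
  d <- dim(img8)
  prB <- lineProfile(img8, c(d[1] / 2 - 2, d[1] / 2 + 2, 1, d[2]),
                     pixelScaleUm = 0.5, normalize = TRUE)
  pk <- which(prB@intensities > 0.95)
  sep <- (max(pk) + min(pk)) / 2  # midpoints of the two plateaus differ by 8
  peaks <- split(pk, cumsum(c(1, diff(pk) > 1)))
  expect_equal(length(peaks), 2)
  centres <- vapply(peaks, function(p) mean(prB@positions[p]), numeric(1))
  expect_equal(abs(unname(diff(centres))), 8, tolerance = 1 / 8)

  expect_error(lineProfile(img, c(10, 5, 1, 60)), "ROI")
  expect_error(lineProfile(img, c(1, 40, 1, 600)), "ROI")
})

test_that("modulation depth matches closed forms and is scale-invariant", {
  square <- rep(rep(c(1, 0), each = 8), 6)
  expect_equal(modulationDepth(square), 1)
  expect_equal(modulationDepth(rep(3, 50)), 0)

  ## full periods ending on maxima, so every valley has unit flanking peaks
  x <- seq(0, 4 * pi, length.out = 601)
  sine <- 0.6 + 0.4 * cos(x)            # min 0.2, max 1.0
  expect_equal(modulationDepth(sine), (1 - 0.2) / (1 + 0.2), tolerance = 0.01)

  ## affine rescaling is undone by profile normalization
  prof <- new("LineProfile", positions = x, intensities = sine,
              normalized = FALSE)
  profScaled <- new("LineProfile", positions = x,
                    intensities = 100 + 7 * sine, normalized = FALSE)
  norm <- function(p) {
    y <- p@intensities
    new("LineProfile", positions = p@positions,
        intensities = (y - min(y)) / diff(range(y)), normalized = TRUE)
  }
  expect_equal(modulationDepth(norm(prof)), modulationDepth(norm(profScaled)))
})

test_that("the resolved-pitch sweep interpolates the threshold crossing", {
  p <- c(4, 8, 10, 12)
  m <- c(0.02, 0.05, 0.30, 0.50)
  ## crossing between 8 (0.05) and 10 (0.30): 8 + 0.05/0.25 * 2
  expect_equal(smallestResolvedPitch(p, m), 8.4)
  expect_error(smallestResolvedPitch(p, c(0.3, 0.4, 0.5, 0.6)),
               "all pitches")
  expect_error(smallestResolvedPitch(p, c(0.01, 0.02, 0.03, 0.04)),
               "unresolved")
})

test_that("peak SNR follows its definition and Poisson scaling", {
  set.seed(42)
  img <- matrix(rnorm(80 * 80, 10, 2), 80, 80)
  img[30:40, 30:40] <- 110               # flat-topped signal block
  snr <- peakSnr(img, c(25, 45, 25, 45), c(1, 20, 1, 20), smoothSigmaPx = 1)
  bg <- img[1:20, 1:20]
  expect_equal(snr, (110 - mean(bg)) / sd(bg), tolerance = 0.02)

  ## pure noise: extreme-value statistic stays in the low single digits
  noise <- matrix(rnorm(100 * 100), 100, 100)
  snrN <- peakSnr(noise, c(1, 40, 1, 100), c(61, 100, 1, 100))
  expect_lt(snrN, 6)

  expect_error(peakSnr(matrix(1, 10, 10), c(1, 5, 1, 5), c(6, 10, 6, 10)),
               "zero variance")
  expect_error(peakSnr(img, c(1, 40, 1, 40), c(20, 60, 20, 60)), "disjoint")

  ## sqrt(averages) scaling on Poisson-dominated simulated frames: wide,
  ## well-separated cores give uniform-valued regions, so the ROI variances
  ## are pure shot noise (no core/gap structural variance). One core sits on
  ## the bead, its neighbours on the dim background.
  wide <- generateBundle(BundleSpec(imagingDiameter = 110,
                                    meanCoreDistance = 50,
                                    coreDiameterMin = 45,
                                    coreDiameterMax = 46,
                                    latticeJitterFrac = 0,
                                    transmissionCV = 0, deadCoreFrac = 0),
                         seed = 1L)
  scene <- makeBeadPhantom(14, centers = matrix(0, 1, 2),
                           windowUm = c(220, 220), background = 0.02)
  snrs <- vapply(c(1L, 4L, 16L), function(av) {
    meta <- AcquisitionMeta(matrix(0, 1, 2), nx = 64L, ny = 64L,
                            pixelScale = 2, averages = av,
                            photonsPerUnit = 250, readSigma = 0,
                            background = 0.05, seed = 8L)
    tile <- acquireTile(scene, wide, meta, 1L)
    ## signal ROI: centre core (on the bead); background ROI: inside the
    ## core centred at (25, 43.3) um -> pixel (col 45, row 54)
    peakSnr(tile, c(29, 36, 29, 36), c(51, 57, 42, 48), smoothSigmaPx = 0)
  }, numeric(1))
  expect_equal(snrs[2] / snrs[1], 2, tolerance = 0.15)
  expect_equal(snrs[3] / snrs[2], 2, tolerance = 0.15)
})

test_that("fidelity metrics are exact on known pairs", {
  truth <- fxTexture(48) + 2
  expect_equal(fidelity(truth, truth)$nrmse, 0)
  expect_equal(fidelity(truth, truth)$ssim, 1)
  neg <- fidelity(-truth + 2 * mean(truth), truth)
  expect_lte(neg$ssim, 0.05)
  expect_error(fidelity(matrix(NA_real_, 4, 4), matrix(1, 4, 4)), "overlap")

  ## mosaic against a scene: flat-scene reconstruction scores high fidelity
  flat <- makeFlatScene(2, c(100, 100), 1)
  img <- matrix(2, 50, 50)
  mos <- new("Mosaic", image = img, weight = matrix(1, 50, 50),
             pixelScale = 1, origin = c(-25, -25), channel = "CARS",
             tileOrigins = matrix(0, 1, 2))
  fd <- fidelity(mos, flat)
  expect_lt(fd$nrmse, 1e-9)
})

test_that("RGB compositing follows the fixed colour coding", {
  a <- matrix(runif(400), 20, 20)
  z <- matrix(0, 20, 20)
  onlyCars <- composeRgb(a, z, z)
  expect_true(all(onlyCars[, , 2] == 0) && all(onlyCars[, , 3] == 0))
  expect_gt(max(onlyCars[, , 1]), 0.9)

  gray <- composeRgb(a, a, a)
  expect_equal(gray[, , 1], gray[, , 2])
  expect_equal(gray[, , 2], gray[, , 3])

  ## percentile scaling saturates at most ~1% per channel
  big <- matrix(rnorm(1e4), 100, 100)
  comp <- composeRgb(big, big, big, probs = c(0.01, 0.99))
  expect_lte(mean(comp[, , 1] == 1), 0.015)
  expect_lte(mean(comp[, , 1] == 0), 0.015)
  sc <- attr(comp, "scaling")
  expect_named(sc, c("CARS", "TPEF", "SHG"))

  expect_error(composeRgb(a, z, matrix(0, 5, 5)), "dimensions")
})

test_that("stripe contrast isolates structure at the known pitch", {
  n <- 120
  xs <- seq_len(n)
  grating <- outer(rep(1, n), ((xs %% 10) < 5) + 0)  # pitch 10 px
  expect_gt(stripeContrast(grating, 10, 1), 0.9)
  expect_equal(stripeContrast(matrix(1, n, n), 10, 1), 0)
  ## structure at a different period folds away
  other <- outer(rep(1, n), sin(2 * pi * xs / 7))
  expect_lt(stripeContrast(other + 2, 10, 1), 0.1)
  expect_error(stripeContrast(grating, 200, 1), "fewer than two")
})
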