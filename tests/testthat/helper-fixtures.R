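## Shared fixtures, built in code and cached per test run. Small bundles and
## scan fields keep the suite fast; the acceptance tests use the full default
## geometry.

.fx <- new.env(parent = emptyenv())

fxCache <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

## small bundle: ~600 cores, default FIGH-like statistics otherwise
fxSpec <- function() BundleSpec(imagingDiameter = 120)

fxMap <- function() fxCache("map", generateBundle(fxSpec(), seed = 7L))

## uniform-transmission bundle for construction checks
fxUniformMap <- function() fxCache("umap",
  generateBundle(BundleSpec(imagingDiameter = 80, transmissionCV = 0,
                            deadCoreFrac = 0), seed = 3L))

fxFlatScene <- function() fxCache("flat", makeFlatScene(1, c(320, 320), 1))

## noise-free acquisition metadata over the fixture bundle
fxMetaClean <- function(positions = matrix(0, 1, 2), nx = 160L, ny = nx,
                        pixelScale = 0.55, seed = 11L, ...) {
  AcquisitionMeta(stagePositions = positions, nx = nx, ny = ny,
                  pixelScale = pixelScale, photonsPerUnit = Inf,
                  readSigma = 0, seed = seed, ...)
}

fxMetaNoisy <- function(positions = matrix(0, 1, 2), nx = 160L, ny = nx,
                        pixelScale = 0.55, seed = 11L, ...) {
  AcquisitionMeta(stagePositions = positions, nx = nx, ny = ny,
                  pixelScale = pixelScale, seed = seed, ...)
}

## wrap bare matrices into a TileStack
fxStackOf <- function(tilesList, pixelScale = 1, positions = NULL) {
  if (is.null(positions)) positions <- matrix(0, length(tilesList), 2)
  meta <- AcquisitionMeta(stagePositions = positions,
                          nx = ncol(tilesList[[1]]), ny = nrow(tilesList[[1]]),
                          pixelScale = pixelScale,
                          photonsPerUnit = Inf, readSigma = 0)
  new("TileStack", tiles = tilesList, meta = meta, coreMap = NULL,
      driftTrace = matrix(numeric(0), 0, 2))
}

## smooth random texture with lattice-free content, for registration tests
fxTexture <- function(n = 96L, seed = 5L, sigma = 2) {
  set.seed(seed)
  as.matrix(EBImage::gblur(matrix(stats::rnorm(n * n), n, n), sigma))
}
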