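## Internal numerical helpers shared across modules.

## Evaluate a function with a locally seeded RNG, restoring the caller's
## stream afterwards. Streams are keyed (seed, index) so tile t of a series
## is reproducible in isolation.
.withSeed <- function(seed, index = 0L, fun) {
  key <- (as.double(seed) * 48271 + as.double(index) * 7919) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(key))
  fun()
}

## Bilinear interpolation of matrix `img` at fractional pixel positions
## (rowPos, colPos), 1-based, pixel centres at integers. Out-of-range -> NA.
## NA pixels propagate.
.bilinear <- function(img, rowPos, colPos) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(rowPos))
  ok <- rowPos >= 1 & rowPos <= nr & colPos >= 1 & colPos <= nc &
    is.finite(rowPos) & is.finite(colPos)
  if (!any(ok)) return(out)
  r <- rowPos[ok]; c <- colPos[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  r0 <- pmax(r0, 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1, c0)]
  i01 <- img[cbind(r0, c0 + 1)]
  i11 <- img[cbind(r0 + 1, c0 + 1)]
  out[ok] <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
  out
}

## Translate an image by (dy, dx) pixels (content moves down/right for
## positive values), bilinear resampling, NA fill outside.
.translate <- function(img, dy, dx) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(seq_len(nr), nr, nc) - dy
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dx
  matrix(.bilinear(img, as.vector(rows), as.vector(cols)), nr, nc)
}

## Flux-preserving (area-average) resize by an isotropic factor < 1, based on
## box sums read off an integral image. Linear interpolation of the integral
## image is exact for box sums of a piecewise-constant image, so the global
## mean is preserved up to NA edge effects. NA pixels are excluded through a
## parallel coverage integral; output pixels with < 50% coverage become NA.
.resizeArea <- function(img, factor) {
  stopifnot(factor > 0)
  if (factor >= 1) return(img)
  nr <- nrow(img); nc <- ncol(img)
  nrOut <- max(1L, round(nr * factor))
  ncOut <- max(1L, round(nc * factor))
  fr <- nr / nrOut; fc <- nc / ncOut   # source pixels per target pixel

  mask <- is.finite(img)
  vals <- img; vals[!mask] <- 0

  intImg <- function(m) {
    s <- apply(m, 2, cumsum)
    s <- t(apply(s, 1, cumsum))
    rbind(0, cbind(0, s))  # S[i+1, j+1] = sum over m[1:i, 1:j]
  }
  ## evaluate integral image at fractional edge positions by separable
  ## linear interpolation
  evalS <- function(S, rEdge, cEdge) {
    r0 <- floor(rEdge); frac <- rEdge - r0
    r0 <- pmin(pmax(r0, 0), nr) ; r1 <- pmin(r0 + 1, nr)
    Sr <- S[r0 + 1, , drop = FALSE] * (1 - frac) + S[r1 + 1, , drop = FALSE] * frac
    c0 <- floor(cEdge); fcc <- cEdge - c0
    c0 <- pmin(pmax(c0, 0), nc); c1 <- pmin(c0 + 1, nc)
    Sr[, c0 + 1, drop = FALSE] * rep(1 - fcc, each = nrow(Sr)) +
      Sr[, c1 + 1, drop = FALSE] * rep(fcc, each = nrow(Sr))
  }
  boxSums <- function(S) {
    rE <- (0:nrOut) * fr; cE <- (0:ncOut) * fc
    G <- evalS(S, rE, cE)
    G[-1, -1, drop = FALSE] - G[-1, -(ncOut + 1), drop = FALSE] -
      G[-(nrOut + 1), -1, drop = FALSE] +
      G[-(nrOut + 1), -(ncOut + 1), drop = FALSE]
  }
  v <- boxSums(intImg(vals))
  w <- boxSums(intImg(mask + 0))
  out <- v / w
  out[w < 0.5 * fr * fc] <- NA_real_
  out
}

## Gaussian blur wrapper (sigma in pixels). EBImage::gblur needs sigma > 0.
.gblur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma,
                           radius = max(3L, 2L * ceiling(3 * sigma) + 1L)))
}

## Radially averaged magnitude spectrum. Returns data.frame(r, power) where
## r is the integer spectral radius in bins (cycles per image extent).
.radialSpectrum <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  w <- outer(wr, wc)
  x <- (img - mean(img)) * w
  F <- Mod(stats::fft(x))
  fy <- c(0:floor(nr / 2), -((ceiling(nr / 2) - 1):1)) / nr
  fx <- c(0:floor(nc / 2), -((ceiling(nc / 2) - 1):1)) / nc
  R <- sqrt(outer(fy^2, fx^2, "+"))  # cycles / pixel
  n <- min(nr, nc)
  rBin <- round(R * n)               # cycles per n-pixel extent
  keep <- rBin <= floor(n / 2)
  agg <- tapply(F[keep], rBin[keep], mean)
  data.frame(r = as.integer(names(agg)), power = as.numeric(agg))
}

## round half away from zero (printed-value convention)
.round <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
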