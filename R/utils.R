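# Internal numerical helpers shared across modules.

.clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## wrap angles to (-pi, pi]
.wrapPi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

.fft2 <- function(m) stats::fft(m)
.ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

## signed DFT sample frequencies in cycles per sample (like fftfreq)
.fftFreq <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

#' Sub-pixel image translation by Fourier phase shift
#'
#' Translates a single-channel image by a (possibly fractional) number of
#' pixels using the Fourier shift theorem. Exact for band-limited images and
#' therefore the reference displacement operator for the synthetic fixtures:
#' a shift by exactly one pixel equals an integer roll of the array.
#' Boundaries wrap circularly.
#'
#' @param img numeric matrix (rows = y, cols = x).
#' @param dx,dy displacement in pixels along x (columns) and y (rows);
#'   positive values move content toward larger x / y.
#' @return matrix of the same dimension.
#' @export
#' @examples
#' m <- matrix(rnorm(64), 8, 8)
#' max(abs(fourierShift(m, 1, 0) - m[, c(8, 1:7)]))  # ~1e-15
fourierShift <- function(img, dx, dy) {
  stopifnot(is.matrix(img))
  H <- nrow(img); W <- ncol(img)
  fy <- .fftFreq(H); fx <- .fftFreq(W)
  ## outer(row-freqs, col-freqs) phase ramp
  ramp <- exp(-2i * pi * (outer(fy * dy, rep(1, W)) + outer(rep(1, H), fx * dx)))
  Re(.ifft2(.fft2(img) * ramp))
}

## 2-D "same" convolution with replicate (edge-clamp) padding.
## Direct shifted-sum evaluation; intended for small kernels.
.conv2 <- function(img, k) {
  kh <- nrow(k); kw <- ncol(k)
  ry <- (kh - 1) %/% 2; rx <- (kw - 1) %/% 2
  H <- nrow(img); W <- ncol(img)
  padY <- c(rep(1, ry), 1:H, rep(H, kh - 1 - ry))
  padX <- c(rep(1, rx), 1:W, rep(W, kw - 1 - rx))
  p <- img[padY, padX, drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_len(kh)) {
    for (j in seq_len(kw)) {
      if (k[i, j] != 0)
        out <- out + k[i, j] * p[(kh - i) + 1:H, (kw - j) + 1:W, drop = FALSE]
    }
  }
  out
}

## FFT-based "same" convolution with replicate padding (for larger kernels,
## e.g. Richardson-Lucy PSFs). Kernel need not be odd-sized.
.conv2fft <- function(img, k) {
  kh <- nrow(k); kw <- ncol(k)
  if (kh * kw <= 49) return(.conv2(img, k))
  H <- nrow(img); W <- ncol(img)
  ry <- kh %/% 2; rx <- kw %/% 2
  padY <- c(rep(1, ry), 1:H, rep(H, ry))
  padX <- c(rep(1, rx), 1:W, rep(W, rx))
  p <- img[padY, padX, drop = FALSE]
  PH <- nrow(p); PW <- ncol(p)
  kp <- matrix(0, PH, PW)
  kp[1:kh, 1:kw] <- k
  ## center the kernel so the output is aligned ("same")
  cy <- (kh - 1) %/% 2; cx <- (kw - 1) %/% 2
  kp <- kp[((0:(PH - 1) + cy) %% PH) + 1, ((0:(PW - 1) + cx) %% PW) + 1]
  full <- Re(.ifft2(.fft2(p) * .fft2(kp)))
  full[ry + 1:H, rx + 1:W, drop = FALSE]
}

## sliding-window sum over a (2r+1) x (2r+1) box, replicate padding
.boxSum <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  padY <- c(rep(1, r), 1:H, rep(H, r))
  padX <- c(rep(1, r), 1:W, rep(W, r))
  p <- m[padY, padX, drop = FALSE]
  cs <- apply(p, 2, cumsum)
  rows <- rbind(cs[2 * r + 1, , drop = FALSE],
                cs[(2 * r + 2):nrow(cs), , drop = FALSE] -
                  cs[1:(nrow(cs) - 2 * r - 1), , drop = FALSE])
  cs2 <- t(apply(rows, 1, cumsum))
  cbind(cs2[, 2 * r + 1, drop = FALSE],
        cs2[, (2 * r + 2):ncol(cs2), drop = FALSE] -
          cs2[, 1:(ncol(cs2) - 2 * r - 1), drop = FALSE])
}

.gaussianKernel <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

## Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
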