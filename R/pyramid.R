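#' @include AllClasses.R utils.R
NULL

#' PyramidDecomposition: complex steerable-pyramid coefficients of a frame
#'
#' Overcomplete multi-scale, multi-orientation decomposition whose
#' band coefficients are complex: their local phase shifts approximately
#' linearly with small spatial translations, which is what phase-based
#' motion magnification manipulates.
#'
#' @slot coeffs list of complex coefficient matrices, one per
#'   (level, orientation) band, level-major order.
#' @slot highpass,lowpass real residual bands.
#' @slot levels,orientations pyramid geometry.
#' @slot dim image dimension \code{c(H, W)}.
#' @exportClass PyramidDecomposition
setClass("PyramidDecomposition",
  representation(coeffs = "list", highpass = "matrix", lowpass = "matrix",
                 levels = "integer", orientations = "integer",
                 dim = "integer"))

## DFT-index mirror: value at -omega for each omega
.mirrorSpec <- function(m) {
  H <- nrow(m); W <- ncol(m)
  m[c(1, H:2), c(1, W:2)]
}

## Frequency-domain steerable-pyramid filters (non-decimated, analytic
## orientation bands on a half-plane). Radial windows are raised cosines
## in log2 radial frequency, an octave per level; angular windows are
## cos^(K-1) lobes. The filter set is normalized pointwise so that
## highpass^2 + lowpass^2 + sum_bands (F^2 + mirror(F)^2) = 1 exactly,
## giving perfect reconstruction.
.pyramidFilters <- function(H, W, levels, orientations) {
  key <- paste(H, W, levels, orientations, sep = "x")
  cache <- .cellmagCache
  if (!is.null(cache[[key]])) return(cache[[key]])
  fy <- .fftFreq(H); fx <- .fftFreq(W)
  FY <- outer(fy, rep(1, W)); FX <- outer(rep(1, H), fx)
  r <- sqrt(FY^2 + FX^2)
  r[1, 1] <- 1e-12
  x <- log2(r / 0.5)            # 0 at Nyquist, -1 one octave down, ...
  theta <- atan2(FY, FX)
  rad <- function(center) {     # raised-cosine bump of half-width 1 octave
    u <- x - center
    w <- matrix(0, H, W)
    sel <- abs(u) < 1
    w[sel] <- cos(pi / 2 * u[sel])
    w
  }
  hi <- matrix(0, H, W)
  hi[x >= 0] <- 1
  sel <- x > -1 & x < 0
  hi[sel] <- cos(pi / 2 * x[sel])
  bands <- lapply(seq_len(levels), function(s) rad(-s))
  lo <- matrix(0, H, W)
  lo[x <= -levels - 1] <- 1
  sel <- x > -levels - 1 & x < -levels
  lo[sel] <- cos(pi / 2 * (x[sel] + levels + 1))
  K <- orientations
  ang <- lapply(seq_len(K), function(k) {
    thk <- pi * (k - 1) / K
    d <- .wrapPi(theta - thk)
    a <- matrix(0, H, W)
    sel <- abs(d) < pi / 2
    a[sel] <- cos(d[sel])^(K - 1)
    a
  })
  filts <- vector("list", levels * K)
  for (s in seq_len(levels))
    for (k in seq_len(K))
      filts[[(s - 1) * K + k]] <- bands[[s]] * ang[[k]]
  total <- hi^2 + lo^2
  for (f in filts) total <- total + f^2 + .mirrorSpec(f)^2
  norm <- sqrt(total)
  out <- list(high = hi / norm, low = lo / norm,
              bands = lapply(filts, function(f) f / norm),
              levels = levels, orientations = K, dim = c(H, W))
  cache[[key]] <- out
  out
}

.cellmagCache <- new.env(parent = emptyenv())

.maxPyramidLevels <- function(H, W) max(1L, floor(log2(min(H, W))) - 2L)

.checkPyramidGeometry <- function(H, W, levels) {
  if (min(H, W) < 2^levels)
    stop("image ", H, " x ", W, " too small for ", levels,
         " pyramid levels; maximum feasible depth is ",
         .maxPyramidLevels(H, W))
}

#' Build the complex steerable pyramid of one frame
#'
#' @param frame numeric H x W single-channel image.
#' @param levels pyramid depth (radial octaves).
#' @param orientations number of orientation bands.
#' @return a \linkS4class{PyramidDecomposition}.
#' @seealso \code{\link{reconstructPyramid}}, \code{\link{magnify}}
#' @export
buildPyramid <- function(frame, levels = 4L, orientations = 4L) {
  stopifnot(is.matrix(frame))
  H <- nrow(frame); W <- ncol(frame)
  .checkPyramidGeometry(H, W, levels)
  filt <- .pyramidFilters(H, W, as.integer(levels), as.integer(orientations))
  fhat <- .fft2(frame)
  coeffs <- lapply(filt$bands, function(f) .ifft2(f * fhat))
  new("PyramidDecomposition", coeffs = coeffs,
      highpass = Re(.ifft2(filt$high * fhat)),
      lowpass = Re(.ifft2(filt$low * fhat)),
      levels = as.integer(levels), orientations = as.integer(orientations),
      dim = c(H, W))
}

#' Reconstruct a frame from its pyramid decomposition
#'
#' Inverts \code{\link{buildPyramid}}; for an unmodified decomposition the
#' round trip reproduces the frame to near machine precision (well within
#' the 1e-3 RMS contract).
#'
#' @param pyr a \linkS4class{PyramidDecomposition}.
#' @return numeric H x W image.
#' @export
reconstructPyramid <- function(pyr) {
  stopifnot(is(pyr, "PyramidDecomposition"))
  filt <- .pyramidFilters(pyr@dim[1], pyr@dim[2], pyr@levels,
                          pyr@orientations)
  acc <- filt$high * .fft2(pyr@highpass) + filt$low * .fft2(pyr@lowpass)
  for (i in seq_along(filt$bands))
    acc <- acc + 2 * filt$bands[[i]] * .fft2(pyr@coeffs[[i]])
  Re(.ifft2(acc))
}
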