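#' @include AllClasses.R utils.R
NULL

#' Temporal mean image over a frame window
#'
#' Pixelwise arithmetic mean of the intensities over a (0-based, half-open)
#' frame window, computed per channel. The mean image is the substrate for
#' edge detection: cells move mainly at their edges, and averaging over
#' time suppresses intensity noise before the spatial gradient is taken.
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param window integer \code{c(t0, t1)}, frames \code{t0 <= t < t1}
#'   (0-based); default the whole video.
#' @return numeric \code{H x W x C} array.
#' @export
temporalMean <- function(video, window = NULL) {
  Tn <- nFrames(video)
  if (is.null(window)) window <- c(0L, Tn)
  window <- as.integer(window)
  if (window[1] < 0L || window[2] > Tn || window[1] >= window[2])
    stop("invalid frame window [", window[1], ", ", window[2],
         "): must be non-empty and within [0, ", Tn, ")")
  sub <- video@frames[(window[1] + 1L):window[2], , , , drop = FALSE]
  colMeans(sub, dims = 1)
}

.sobelKx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8
.prewittKx <- matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3) / 6

## gradient magnitude of a single-channel image under a named operator;
## kernels are scaled so the response approximates intensity change per px
.gradientMagnitude <- function(img, method) {
  switch(method,
    sobel = {
      gx <- .conv2(img, .sobelKx)
      gy <- .conv2(img, t(.sobelKx))
      sqrt(gx^2 + gy^2)
    },
    prewitt = {
      gx <- .conv2(img, .prewittKx)
      gy <- .conv2(img, t(.prewittKx))
      sqrt(gx^2 + gy^2)
    },
    roberts = {
      g1 <- .conv2(img, matrix(c(1, 0, 0, -1), 2, 2))
      g2 <- .conv2(img, matrix(c(0, 1, -1, 0), 2, 2))
      sqrt(g1^2 + g2^2) / sqrt(2)
    },
    stop("no gradient magnitude for method '", method, "'"))
}

## zero crossings of a filtered response, with a minimum jump threshold
.zeroCross <- function(L, thresh) {
  H <- nrow(L); W <- ncol(L)
  out <- matrix(FALSE, H, W)
  right <- cbind(L[, -1], L[, W])
  down <- rbind(L[-1, ], L[H, ])
  out <- out | (L * right < 0 & abs(L - right) > thresh)
  out <- out | (L * down < 0 & abs(L - down) > thresh)
  left <- cbind(L[, 1], L[, -W])
  up <- rbind(L[1, ], L[-H, ])
  out <- out | (L * left < 0 & abs(L - left) > thresh)
  out <- out | (L * up < 0 & abs(L - up) > thresh)
  out
}

.logKernel <- function(sigma = 2, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  X <- outer(rep(1, length(x)), x)
  Y <- t(X)
  r2 <- X^2 + Y^2
  k <- (r2 - 2 * sigma^2) / sigma^4 * exp(-r2 / (2 * sigma^2))
  k - mean(k)
}

.cannyMask <- function(img, gth) {
  sm <- .conv2(img, .gaussianKernel(1.4))
  gx <- .conv2(sm, .sobelKx)
  gy <- .conv2(sm, t(.sobelKx))
  mag <- sqrt(gx^2 + gy^2)
  H <- nrow(mag); W <- ncol(mag)
  ang <- atan2(gy, gx)                    # gradient direction
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mag
  nb <- function(dy, dx) pad[2:(H + 1) + dy, 2:(W + 1) + dx]
  ## non-maximum suppression along the gradient direction
  keep <- (sector == 0 & mag >= nb(0, 1) & mag >= nb(0, -1)) |
          (sector == 1 & mag >= nb(1, 1) & mag >= nb(-1, -1)) |
          (sector == 2 & mag >= nb(1, 0) & mag >= nb(-1, 0)) |
          (sector == 3 & mag >= nb(1, -1) & mag >= nb(-1, 1))
  thin <- mag * keep
  ## hysteresis: keep weak-edge components touching a strong edge
  strong <- thin > gth
  weak <- thin > 0.4 * gth
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak)
  keepLabs <- unique(lab[strong])
  matrix(lab %in% keepLabs[keepLabs > 0], H, W)
}

.binaryEdgeMap <- function(img, method, gth) {
  switch(method,
    canny = .cannyMask(img, gth),
    log = .zeroCross(.conv2(img, .logKernel(2)), gth),
    zerocross = .zeroCross(.conv2(img, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0),
                                              3, 3)), gth),
    stop("no binary edge map for method '", method, "'"))
}

#' Detect edge pixels on the temporal-mean image
#'
#' A pixel is an edge pixel when the spatial gradient magnitude of the
#' temporal-mean image exceeds \code{gth} in every analyzed channel
#' (operators \code{sobel}, \code{prewitt}, \code{roberts}), or when the
#' named edge algorithm's own binary map is true (\code{canny},
#' \code{log}, \code{zerocross}, which embed their own thresholding;
#' \code{gth} is passed through as their threshold parameter, with Canny
#' hysteresis using \code{(0.4 * gth, gth)}). Multi-channel masks are
#' intersected, so the edge set is an edge in every channel.
#'
#' \code{gth} is expressed on normalized \code{[0, 1]} intensities, making
#' it independent of the acquisition bit depth.
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param gth gradient threshold (>= 0).
#' @param method one of \code{"sobel"} (default), \code{"prewitt"},
#'   \code{"roberts"}, \code{"log"}, \code{"zerocross"}, \code{"canny"}.
#' @param window 0-based half-open frame window for the temporal mean;
#'   default the whole video.
#' @return an \linkS4class{EdgeMask}.
#' @export
detectEdges <- function(video, gth, method = c("sobel", "prewitt", "roberts",
                                               "log", "zerocross", "canny"),
                        window = NULL) {
  method <- match.arg(method)
  stopifnot(gth >= 0)
  if (is.null(window)) window <- c(0L, nFrames(video))
  mi <- temporalMean(video, window)
  C <- dim(mi)[3]
  mask <- matrix(TRUE, dim(mi)[1], dim(mi)[2])
  gradientBased <- method %in% c("sobel", "prewitt", "roberts")
  for (ch in seq_len(C)) {
    m <- if (gradientBased)
      .gradientMagnitude(mi[, , ch], method) > gth
    else
      .binaryEdgeMap(mi[, , ch], method, gth)
    mask <- mask & m
  }
  new("EdgeMask", mask = mask, meanImage = mi, gth = as.numeric(gth),
      method = method, window = as.integer(window))
}

#' Edge-pixel coordinates of an EdgeMask
#'
#' @param edgeMask an \linkS4class{EdgeMask}.
#' @return data.frame with 0-based columns \code{x}, \code{y}.
#' @export
edgeCoords <- function(edgeMask) {
  idx <- which(edgeMask@mask, arr.ind = TRUE)
  data.frame(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}
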