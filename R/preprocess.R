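#' @include AllClasses.R utils.R videoio.R
NULL

## one Richardson-Lucy image update; K and its adjoint (flipped kernel)
.rlStep <- function(est, data, K, Kt) {
  denom <- .conv2fft(est, K)
  denom[denom < 1e-12] <- 1e-12
  est * .conv2fft(data / denom, Kt)
}

.flipKernel <- function(k) k[nrow(k):1, ncol(k):1, drop = FALSE]

## blind RL: alternate image and PSF updates from one frame,
## starting from a flat kernel
.blindEstimatePSF <- function(frame, psfSize, iterations) {
  K <- matrix(1 / psfSize^2, psfSize, psfSize)
  est <- frame
  for (i in seq_len(iterations)) {
    est <- .rlStep(est, frame, K, .flipKernel(K))
    ## PSF update: RL in the kernel domain (image acts as the kernel)
    denom <- .conv2fft(est, K)
    denom[denom < 1e-12] <- 1e-12
    ratio <- frame / denom
    ## kernel-domain RL step: correlate ratio with the image estimate
    ## at every kernel offset
    r <- (psfSize - 1L) %/% 2L
    H <- nrow(frame); W <- ncol(frame)
    upd <- matrix(0, psfSize, psfSize)
    for (dy in -r:r) for (dx in -r:r) {
      ys <- max(1, 1 - dy):min(H, H - dy)
      xs <- max(1, 1 - dx):min(W, W - dx)
      upd[dy + r + 1, dx + r + 1] <-
        sum(est[ys, xs] * ratio[ys + dy, xs + dx]) / sum(est[ys, xs])
    }
    K <- K * upd
    K[K < 0] <- 0
    K <- K / sum(K)
  }
  K
}

#' Richardson-Lucy deconvolution of every frame
#'
#' Reverses the blur the microscope's point spread function imposes on
#' each frame, using multiplicative Richardson-Lucy iterations (which
#' preserve nonnegativity). With a measured PSF the kernel is applied
#' as given; without one, blind mode first estimates the PSF from the
#' first frame by alternating image and kernel updates from a flat
#' initial guess, then applies it to all frames. Frames are processed
#' independently and the output is clipped to [0, 1].
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param psf a \linkS4class{PSFModel}, or \code{NULL} for blind
#'   estimation.
#' @param iterations Richardson-Lucy iteration count (>= 1; default 10).
#' @param psfSize blind-mode initial kernel size (odd; default 7).
#' @return the deconvolved \linkS4class{VideoSequence}.
#' @export
deconvolve <- function(video, psf = NULL, iterations = 10L, psfSize = 7L) {
  stopifnot(is(video, "VideoSequence"))
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1")
  d <- frameDim(video)
  if (is.null(psf)) {
    if (psfSize >= min(d)) stop("blind PSF size must be smaller than the frame")
    K <- .blindEstimatePSF(matrix(video@frames[1, , , 1], d[1]),
                           as.integer(psfSize), iterations)
    psf <- psfModel(K, "blind-estimated")
  }
  K <- psf@kernel
  if (nrow(K) >= d[1] || ncol(K) >= d[2])
    stop("PSF kernel (", nrow(K), " x ", ncol(K),
         ") must be smaller than the frame (", d[1], " x ", d[2], ")")
  Kt <- .flipKernel(K)
  out <- video@frames
  for (ch in seq_len(nChannels(video))) {
    for (t in seq_len(nFrames(video))) {
      data <- matrix(video@frames[t, , , ch], d[1])
      est <- data
      est[est < 1e-6] <- 1e-6
      for (i in seq_len(iterations)) est <- .rlStep(est, data, K, Kt)
      out[t, , , ch] <- est
    }
  }
  out[out < 0] <- 0
  out <- .clip01(out)
  new("VideoSequence", frames = out, frameRate = video@frameRate,
      pixelSize = video@pixelSize, channelNames = video@channelNames)
}

## ---- stabilization -------------------------------------------------------

## Harris corners of a single-channel image; returns 0-based (x, y)
.harrisCorners <- function(img, maxFeatures = 150L, margin = 12L) {
  gx <- .conv2(img, .sobelKx)
  gy <- .conv2(img, t(.sobelKx))
  Sxx <- .boxSum(gx * gx, 2L); Syy <- .boxSum(gy * gy, 2L)
  Sxy <- .boxSum(gx * gy, 2L)
  R <- Sxx * Syy - Sxy^2 - 0.04 * (Sxx + Syy)^2
  H <- nrow(img); W <- ncol(img)
  ## 3x3 local maxima
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- R
  isMax <- matrix(TRUE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    isMax <- isMax & R >= pad[2:(H + 1) + dy, 2:(W + 1) + dx]
  }
  isMax[1:margin, ] <- FALSE; isMax[(H - margin):H, ] <- FALSE
  isMax[, 1:margin] <- FALSE; isMax[, (W - margin):W] <- FALSE
  idx <- which(isMax & R > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(cbind(x = integer(0), y = integer(0)))
  ord <- order(R[idx], decreasing = TRUE)
  idx <- idx[ord[seq_len(min(maxFeatures, nrow(idx)))], , drop = FALSE]
  cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

## zero-mean NCC of two equal-size patches
.zncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den < 1e-12) return(0)
  sum(a * b) / den
}

## track reference corners into a frame by local NCC search with
## parabolic sub-pixel refinement; init = integer (dx, dy) prior
.trackCorners <- function(ref, frame, corners, patch = 5L, search = 4L,
                          init = c(0L, 0L)) {
  H <- nrow(ref); W <- ncol(ref)
  out <- matrix(NA_real_, nrow(corners), 2)
  for (i in seq_len(nrow(corners))) {
    cx <- corners[i, 1] + 1L; cy <- corners[i, 2] + 1L  # 1-based
    ys <- (cy - patch):(cy + patch); xs <- (cx - patch):(cx + patch)
    tmpl <- ref[ys, xs]
    best <- -Inf; bdx <- NA; bdy <- NA
    scores <- matrix(NA_real_, 2 * search + 1, 2 * search + 1)
    for (dy in -search:search) for (dx in -search:search) {
      y2 <- ys + dy + init[2]; x2 <- xs + dx + init[1]
      if (min(y2) < 1 || max(y2) > H || min(x2) < 1 || max(x2) > W) next
      s <- .zncc(tmpl, frame[y2, x2])
      scores[dy + search + 1, dx + search + 1] <- s
      if (s > best) { best <- s; bdx <- dx; bdy <- dy }
    }
    if (!is.finite(best) || best < 0.3) next
    ## parabolic sub-pixel refinement on the score surface
    sx <- 0; sy <- 0
    iy <- bdy + search + 1; ix <- bdx + search + 1
    if (ix > 1 && ix < ncol(scores) &&
        all(is.finite(scores[iy, ix + c(-1, 1)]))) {
      den <- scores[iy, ix - 1] - 2 * scores[iy, ix] + scores[iy, ix + 1]
      if (den < -1e-12) sx <- 0.5 * (scores[iy, ix - 1] -
                                       scores[iy, ix + 1]) / den
    }
    if (iy > 1 && iy < nrow(scores) &&
        all(is.finite(scores[iy + c(-1, 1), ix]))) {
      den <- scores[iy - 1, ix] - 2 * scores[iy, ix] + scores[iy + 1, ix]
      if (den < -1e-12) sy <- 0.5 * (scores[iy - 1, ix] -
                                       scores[iy + 1, ix]) / den
    }
    out[i, ] <- c(corners[i, 1] + init[1] + bdx + sx,
                  corners[i, 2] + init[2] + bdy + sy)
  }
  out
}

## least-squares similarity transform src -> dst:
## x' = a x - b y + tx ; y' = b x + a y + ty
.fitSimilarity <- function(src, dst) {
  n <- nrow(src)
  A <- rbind(cbind(src[, 1], -src[, 2], rep(1, n), rep(0, n)),
             cbind(src[, 2], src[, 1], rep(0, n), rep(1, n)))
  b <- c(dst[, 1], dst[, 2])
  p <- stats::lm.fit(A, b)$coefficients
  list(a = p[1], b = p[2], tx = p[3], ty = p[4])
}

.applySimilarity <- function(tr, pts)
  cbind(tr$a * pts[, 1] - tr$b * pts[, 2] + tr$tx,
        tr$b * pts[, 1] + tr$a * pts[, 2] + tr$ty)

## RANSAC similarity estimation from matched points
.robustSimilarity <- function(src, dst, tol = 1, iters = 50L) {
  n <- nrow(src)
  if (n < 2L) return(NULL)
  bestInl <- rep(FALSE, n)
  for (i in seq_len(iters)) {
    s <- sample.int(n, 2L)
    if (sum((src[s[1], ] - src[s[2], ])^2) < 1e-9) next
    tr <- .fitSimilarity(src[s, , drop = FALSE], dst[s, , drop = FALSE])
    res <- sqrt(rowSums((.applySimilarity(tr, src) - dst)^2))
    inl <- res < tol
    if (sum(inl) > sum(bestInl)) bestInl <- inl
  }
  if (sum(bestInl) < 2L) return(NULL)
  .fitSimilarity(src[bestInl, , drop = FALSE], dst[bestInl, , drop = FALSE])
}

## centered moving average that shrinks symmetrically at the ends
## (preserves linear trends everywhere)
.smoothCentered <- function(x, window) {
  hw <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    h <- min(hw, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1))
}

## bilinear sampling of img at 0-based fractional coords; fill outside
.bilinearSample <- function(img, xs, ys, fill) {
  H <- nrow(img); W <- ncol(img)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 0 & x0 <= W - 2 & y0 >= 0 & y0 <= H - 2
  x0c <- pmin(pmax(x0, 0), W - 2); y0c <- pmin(pmax(y0, 0), H - 2)
  i00 <- img[cbind(y0c + 1, x0c + 1)]
  i01 <- img[cbind(y0c + 1, x0c + 2)]
  i10 <- img[cbind(y0c + 2, x0c + 1)]
  i11 <- img[cbind(y0c + 2, x0c + 2)]
  v <- (1 - fy) * ((1 - fx) * i00 + fx * i01) +
    fy * ((1 - fx) * i10 + fx * i11)
  v[!ok] <- fill
  v
}

## translation between two frames by phase correlation (integer peak +
## centroid refinement); used to report residual shake
.globalShift <- function(f1, f2) {
  X <- .fft2(f1) * Conj(.fft2(f2))
  Xn <- X / pmax(Mod(X), 1e-12)
  r <- Re(.ifft2(Xn))
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  H <- nrow(r); W <- ncol(r)
  dy <- pk[1] - 1; dx <- pk[2] - 1
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  c(dx = -dx, dy = -dy)
}

#' Feature-matching video stabilization
#'
#' Removes rigid shake or drift: salient (Harris) corner points are
#' collected on the reference frame, matched into every frame by local
#' normalized cross-correlation with sub-pixel refinement, a similarity
#' transform (translation + rotation + scale) is robustly estimated from
#' the noisy correspondences by RANSAC, the transform sequence is
#' temporally smoothed by a centered moving average, and each frame is
#' warped onto the reference with bilinear interpolation (out-of-frame
#' pixels filled with the frame's median intensity, so no spurious border
#' edges feed later edge detection).
#'
#' Frames in which fewer than \code{minFeatures} corners can be matched
#' keep the previous frame's transform, with a warning.
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param reference reference frame index (1-based, default 1).
#' @param smoothWindow moving-average window for the transform sequence
#'   (frames, default 5).
#' @param minFeatures minimum matched corners per frame (default 10).
#' @param maxFeatures corners detected on the reference (default 150).
#' @param search half-width of the per-frame search window in pixels.
#' @param channel channel used for feature matching.
#' @return a \linkS4class{StabilizationResult}.
#' @export
stabilize <- function(video, reference = 1L, smoothWindow = 5L,
                      minFeatures = 6L, maxFeatures = 150L, search = 4L,
                      channel = 1L) {
  stopifnot(is(video, "VideoSequence"))
  Tn <- nFrames(video)
  reference <- as.integer(reference)
  if (reference < 1L || reference > Tn) stop("invalid reference index")
  d <- frameDim(video)
  ref <- matrix(video@frames[reference, , , channel], d[1])
  corners <- .harrisCorners(ref, maxFeatures, margin = 5L + search + 2L)
  if (nrow(corners) < 2L)
    stop("too few salient points on the reference frame to stabilize")
  src <- cbind(corners[, 1], corners[, 2])
  pars <- data.frame(frame = seq_len(Tn), a = 1, b = 0, tx = 0, ty = 0)
  prevInit <- c(0L, 0L)
  prev <- list(a = 1, b = 0, tx = 0, ty = 0)
  for (t in seq_len(Tn)) {
    if (t == reference) { prevInit <- c(0L, 0L); next }
    fr <- matrix(video@frames[t, , , channel], d[1])
    dst <- .trackCorners(ref, fr, corners, search = search, init = prevInit)
    ok <- stats::complete.cases(dst)
    tr <- if (sum(ok) >= max(2L, minFeatures))
      .robustSimilarity(src[ok, , drop = FALSE], dst[ok, , drop = FALSE])
    else NULL
    if (is.null(tr)) {
      warning("frame ", t, ": fewer than ", minFeatures,
              " matched features; keeping previous transform")
      tr <- prev
    }
    pars[t, c("a", "b", "tx", "ty")] <- unlist(tr)
    prev <- tr
    prevInit <- round(c(tr$tx, tr$ty))
  }
  ## temporal smoothing of the transform sequence
  for (cn in c("a", "b", "tx", "ty"))
    pars[[cn]] <- .smoothCentered(pars[[cn]], as.integer(smoothWindow))
  ## warp each frame onto the reference: sample at the forward-mapped
  ## position of each reference pixel
  xs0 <- rep(0:(d[2] - 1), each = d[1])
  ys0 <- rep(0:(d[1] - 1), times = d[2])
  out <- video@frames
  for (t in seq_len(Tn)) {
    tr <- as.list(pars[t, c("a", "b", "tx", "ty")])
    mapped <- .applySimilarity(tr, cbind(xs0, ys0))
    for (ch in seq_len(nChannels(video))) {
      img <- matrix(video@frames[t, , , ch], d[1])
      out[t, , , ch] <- matrix(
        .bilinearSample(img, mapped[, 1], mapped[, 2], stats::median(img)),
        d[1], d[2])
    }
  }
  stab <- new("VideoSequence", frames = out, frameRate = video@frameRate,
              pixelSize = video@pixelSize,
              channelNames = video@channelNames)
  residual <- vapply(seq_len(Tn - 1L), function(t) {
    sh <- .globalShift(matrix(out[t, , , channel], d[1]),
                       matrix(out[t + 1L, , , channel], d[1]))
    sqrt(sum(sh^2))
  }, numeric(1))
  ## dx, dy, rot, scale: estimated motion of each frame relative to the
  ## reference; the warp applied above is its inverse
  transforms <- data.frame(
    frame = pars$frame,
    dx = pars$tx, dy = pars$ty,
    rot_deg = atan2(pars$b, pars$a) * 180 / pi,
    scale = sqrt(pars$a^2 + pars$b^2))
  new("StabilizationResult", video = stab, transforms = transforms,
      residual = residual, reference = reference)
}
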