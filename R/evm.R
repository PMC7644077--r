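#' @include AllClasses.R utils.R pyramid.R
NULL

## squared magnitude response of a second-order band-pass resonator,
## i.e. the zero-phase gain of forward-backward filtering; unity at the
## center frequency, zero at DC
.bandpassGain <- function(freqsHz, centerFreq, halfBand) {
  w <- 2 * pi * abs(freqsHz)
  w0 <- 2 * pi * centerFreq
  B <- 2 * pi * 2 * halfBand
  (B * w)^2 / ((w0^2 - w^2)^2 + (B * w)^2)
}

## circular Gaussian convolution of each column of a (H*W) x n matrix
## interpreted as images, via a cached frequency-domain kernel
.gaussHatCached <- function(H, W, sigma) {
  key <- paste("g", H, W, sigma, sep = "x")
  if (!is.null(.cellmagCache[[key]])) return(.cellmagCache[[key]])
  r <- ceiling(3 * sigma)
  k <- .gaussianKernel(sigma, r)
  kp <- matrix(0, H, W)
  n <- 2 * r + 1
  kp[1:n, 1:n] <- k
  kp <- kp[((0:(H - 1) + r) %% H) + 1, ((0:(W - 1) + r) %% W) + 1]
  ghat <- Re(.fft2(kp))
  .cellmagCache[[key]] <- ghat
  ghat
}

.gaussSmooth <- function(img, ghat) Re(.ifft2(.fft2(img) * ghat))

#' Phase-based Eulerian motion magnification
#'
#' Amplifies motion at a chosen temporal frequency: each frame is
#' decomposed into a complex steerable pyramid, the local phase of every
#' band is unwrapped over time, band-pass filtered around
#' \code{centerFreq} (zero-phase second-order band-pass applied along the
#' temporal DFT), optionally smoothed spatially with amplitude weighting
#' for noise robustness, multiplied by \code{alpha} and added back before
#' reconstruction. Small displacements grow by a factor of approximately
#' \code{1 + alpha}; amplitude noise is left unamplified, which is the
#' point of operating on phase.
#'
#' Multi-channel videos are processed channel by channel. Output is
#' clipped to [0, 1]. \code{alpha = 0} returns the input within
#' reconstruction tolerance.
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param params a \linkS4class{MagnificationParams}; the band
#'   \code{[centerFreq - halfBand, centerFreq + halfBand]} must lie within
#'   (0, Nyquist].
#' @return the amplified-motion \linkS4class{VideoSequence}.
#' @export
magnify <- function(video, params) {
  stopifnot(is(video, "VideoSequence"), is(params, "MagnificationParams"))
  validObject(params)
  fps <- frameRate(video)
  if (params@centerFreq + params@halfBand > fps / 2 + 1e-9)
    stop("amplification band [", params@centerFreq - params@halfBand, ", ",
         params@centerFreq + params@halfBand,
         "] Hz exceeds the Nyquist frequency ", fps / 2, " Hz")
  d <- frameDim(video)
  .checkPyramidGeometry(d[1], d[2], params@levels)
  out <- video@frames
  for (ch in seq_len(nChannels(video)))
    out[, , , ch] <- .magnifyChannel(video@frames[, , , ch], fps, params)
  out <- .clip01(out)
  new("VideoSequence", frames = out, frameRate = video@frameRate,
      pixelSize = video@pixelSize, channelNames = video@channelNames)
}

## fr: T x H x W array of one channel
.magnifyChannel <- function(fr, fps, params) {
  Tn <- dim(fr)[1]; H <- dim(fr)[2]; W <- dim(fr)[3]
  filt <- .pyramidFilters(H, W, params@levels, params@orientations)
  fhat <- vector("list", Tn)
  for (t in seq_len(Tn)) fhat[[t]] <- .fft2(matrix(fr[t, , ], H, W))
  ## residual bands pass through unmodified
  passthrough <- filt$high^2 + filt$low^2
  acc <- lapply(seq_len(Tn), function(t) passthrough * fhat[[t]])
  gain <- .bandpassGain(.fftFreq(Tn) * fps, params@centerFreq,
                        params@halfBand)
  ghat <- if (params@sigmaSpatial > 0)
    .gaussHatCached(H, W, params@sigmaSpatial) else NULL
  npix <- H * W
  for (b in seq_along(filt$bands)) {
    Fb <- filt$bands[[b]]
    coef <- vector("list", Tn)
    phi <- matrix(0, Tn, npix)
    for (t in seq_len(Tn)) {
      c0 <- .ifft2(Fb * fhat[[t]])
      coef[[t]] <- c0
      phi[t, ] <- Arg(c0)
    }
    ## temporal phase unwrapping: cumulate wrapped frame-to-frame steps
    if (Tn > 1) {
      dphi <- .wrapPi(phi[-1, , drop = FALSE] - phi[-Tn, , drop = FALSE])
      phi <- rbind(phi[1, ], apply(dphi, 2, cumsum) +
                     matrix(phi[1, ], Tn - 1, npix, byrow = TRUE))
    }
    ## zero-phase temporal band-pass around the chosen frequency
    delta <- Re(stats::mvfft(stats::mvfft(phi) * gain, inverse = TRUE)) / Tn
    if (params@alpha > 0) {
      for (t in seq_len(Tn)) {
        dphase <- matrix(delta[t, ], H, W)
        if (!is.null(ghat)) {
          A2 <- Mod(coef[[t]])^2
          dphase <- .gaussSmooth(dphase * A2, ghat) /
            (.gaussSmooth(A2, ghat) + 1e-12)
        }
        cmod <- coef[[t]] * exp(1i * params@alpha * dphase)
        acc[[t]] <- acc[[t]] + 2 * Fb * .fft2(cmod)
      }
    } else {
      for (t in seq_len(Tn))
        acc[[t]] <- acc[[t]] + 2 * Fb * .fft2(coef[[t]])
    }
  }
  out <- array(0, dim = c(Tn, H, W))
  for (t in seq_len(Tn)) out[t, , ] <- Re(.ifft2(acc[[t]]))
  out
}
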