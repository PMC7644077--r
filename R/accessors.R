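#' @include AllGenerics.R
NULL

#' @describeIn VideoSequence-class the raw T x H x W x C intensity array
#' @param x object
#' @export
setMethod("frames", "VideoSequence", function(x) x@frames)

#' @describeIn VideoSequence-class frames per second
#' @export
setMethod("frameRate", "VideoSequence", function(x) x@frameRate)

#' @describeIn VideoSequence-class microns per pixel (may be NA)
#' @export
setMethod("pixelSize", "VideoSequence", function(x) x@pixelSize)

#' @describeIn VideoSequence-class channel labels
#' @export
setMethod("channelNames", "VideoSequence", function(x) x@channelNames)

#' @describeIn VideoSequence-class number of frames T
#' @export
setMethod("nFrames", "VideoSequence", function(x) dim(x@frames)[1])

#' @describeIn VideoSequence-class number of channels C
#' @export
setMethod("nChannels", "VideoSequence", function(x) dim(x@frames)[4])

#' @describeIn VideoSequence-class image dimension c(H, W)
#' @export
setMethod("frameDim", "VideoSequence", function(x) dim(x@frames)[2:3])

#' @describeIn VideoSequence-class one frame as an H x W x C array
#' @param t frame index (1-based)
#' @export
setMethod("getFrame", "VideoSequence", function(x, t) {
  stopifnot(t >= 1, t <= nFrames(x))
  x@frames[t, , , , drop = TRUE]
})

#' @describeIn VideoSequence-class intensity series of pixel (px, py)
#'   (0-based coordinates) in one channel
#' @param px,py 0-based pixel coordinates
#' @param channel channel index (1-based)
#' @export
setMethod("pixelSeries", "VideoSequence", function(x, px, py, channel = 1L) {
  d <- frameDim(x)
  stopifnot(px >= 0, px < d[2], py >= 0, py < d[1])
  x@frames[, py + 1L, px + 1L, channel]
})

setMethod("show", "VideoSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VideoSequence: %d frames of %d x %d, %d channel(s) [%s]\n",
              d[1], d[2], d[3], d[4],
              paste(object@channelNames, collapse = ", ")))
  cat(sprintf("  frame rate %.4g Hz (Nyquist %.4g Hz), duration %.4g s\n",
              object@frameRate, object@frameRate / 2,
              d[1] / object@frameRate))
  if (!is.na(object@pixelSize))
    cat(sprintf("  pixel size %.4g um\n", object@pixelSize))
})

#' @describeIn EdgeMask-class number of edge pixels M
#' @param x object
#' @export
setMethod("edgeCount", "EdgeMask", function(x) sum(x@mask))

setMethod("show", "EdgeMask", function(object) {
  cat(sprintf("EdgeMask: %d edge pixels of %d x %d (%s, gth = %.4g)\n",
              sum(object@mask), nrow(object@mask), ncol(object@mask),
              object@method, object@gth))
})

#' @describeIn PowerSpectrum-class dominant non-DC frequency in Hz
#' @param x object
#' @export
setMethod("dominantFreq", "PowerSpectrum", function(x) x@dominantFreq)

#' @describeIn PowerSpectrum-class period of the dominant oscillation in
#'   seconds (1 / dominant frequency)
#' @export
setMethod("dominantPeriod", "PowerSpectrum", function(x) 1 / x@dominantFreq)

#' @describeIn PowerSpectrum-class the spectrum as a data.frame
#'   (freq_hz, power)
#' @export
setMethod("spectrumTable", "PowerSpectrum", function(x)
  data.frame(freq_hz = x@freqs, power = x@power))

setMethod("show", "PowerSpectrum", function(object) {
  cat(sprintf("PowerSpectrum: %d bins to %.4g Hz (L = %d, M = %d pixels)\n",
              length(object@freqs), max(object@freqs), object@L, object@M))
  cat(sprintf("  dominant frequency %.4g Hz (period %.4g s), %.1f%% above mean non-DC power\n",
              object@dominantFreq, 1 / object@dominantFreq,
              object@dominantProminence))
})

#' @describeIn StabilizationResult-class per-frame similarity transforms
#' @param x object
#' @export
setMethod("transforms", "StabilizationResult", function(x) x@transforms)

setMethod("show", "StabilizationResult", function(object) {
  tr <- object@transforms
  cat(sprintf("StabilizationResult: %d frames onto reference %d\n",
              nrow(tr), object@reference))
  cat(sprintf("  max |translation| %.3g px, mean residual %.3g px/frame\n",
              max(abs(c(tr$dx, tr$dy))), mean(object@residual)))
})

setMethod("show", "MotionGrid", function(object) {
  cat(sprintf("MotionGrid: %d segments (l = %d) on %d x %d\n",
              length(object@segments), object@l, object@dim[1],
              object@dim[2]))
})

setMethod("show", "MotionDirector", function(object) {
  cat(sprintf("MotionDirector at (%d, %d): theta_d = %g deg, motion sum %.4g\n",
              object@center[1], object@center[2], object@thetaDeg,
              object@motionSum))
  print(round(object@scores, 6))
})

setMethod("show", "PhasedKymograph", function(object) {
  cat(sprintf("PhasedKymograph: %d x %d along %g deg at (%d, %d); %d expansion / %d contraction frames\n",
              nrow(object@image), ncol(object@image), object@thetaDeg,
              object@center[1], object@center[2],
              sum(object@phaseSign > 0), sum(object@phaseSign < 0)))
})

#' @describeIn MotionBudget-class the scalar degree of motion
#' @param x object
#' @export
setMethod("degreeOfMotionValue", "MotionBudget", function(x) x@degreeOfMotion)

setMethod("show", "MotionBudget", function(object) {
  cat(sprintf("MotionBudget: degree of motion %.6g (noise threshold %g%s)\n",
              object@degreeOfMotion, object@noiseThreshold,
              if (is.na(object@alpha)) "" else
                sprintf(", alpha = %g", object@alpha)))
})

setMethod("show", "NoiseFloorCurve", function(object) {
  cat("NoiseFloorCurve:\n")
  print(object@table, row.names = FALSE)
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf("FixtureSpec '%s': %d x %d, %d frames @ %g fps, f = %g Hz, a = %g px, noise sd %g, seed %d\n",
              object@kind, object@size[1], object@size[2], object@frames,
              object@frameRate, object@motionFreq, object@amplitudePx,
              object@noiseSigma, object@seed))
})
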