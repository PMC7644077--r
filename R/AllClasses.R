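#' @import methods
NULL

#' VideoSequence: a time-lapse microscopy clip with acquisition metadata
#'
#' The universal currency of the pipeline: a \code{T x H x W x C} array of
#' pixel intensities in \code{[0, 1]} together with the frame rate (Hz),
#' the physical pixel size (microns, optional metadata) and channel labels.
#' All pixel coordinates in the package API are 0-based with \code{x} along
#' columns and \code{y} along rows; rectangular regions are half-open.
#'
#' @slot frames numeric array, \code{dim = c(T, H, W, C)}.
#' @slot frameRate frames per second; must be positive. Frequency analysis
#'   is meaningless without it, so it is mandatory.
#' @slot pixelSize microns per pixel, or \code{NA} when unknown.
#' @slot channelNames character vector of length \code{C}.
#' @exportClass VideoSequence
setClass("VideoSequence",
  representation(frames = "array", frameRate = "numeric",
                 pixelSize = "numeric", channelNames = "character"),
  prototype(pixelSize = NA_real_))

setValidity("VideoSequence", function(object) {
  d <- dim(object@frames)
  msg <- character()
  if (length(d) != 4L)
    return("frames must be a T x H x W x C array")
  if (d[1] < 2L) msg <- c(msg, "a video needs at least 2 frames")
  if (d[2] < 8L || d[3] < 8L) msg <- c(msg, "frames must be at least 8 x 8")
  if (d[4] < 1L) msg <- c(msg, "at least one channel required")
  if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    msg <- c(msg, "frameRate must be a single positive number")
  if (length(object@channelNames) != d[4])
    msg <- c(msg, "channelNames length must equal the number of channels")
  if (anyNA(object@frames)) msg <- c(msg, "frames contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct a VideoSequence
#'
#' @param frames numeric array \code{T x H x W x C}; a 3-d \code{T x H x W}
#'   array is promoted to a single-channel video. Integer-typed arrays are
#'   rescaled to \code{[0, 1]} by the maximum representable value of
#'   \code{bitDepth}.
#' @param frameRate frames per second (mandatory, > 0).
#' @param pixelSize microns per pixel (metadata only).
#' @param channelNames optional channel labels; defaults to
#'   \code{"ch1" ... "chC"}.
#' @param bitDepth bit depth used to normalize integer input (default 16).
#' @return a \linkS4class{VideoSequence}.
#' @export
VideoSequence <- function(frames, frameRate, pixelSize = NA_real_,
                          channelNames = NULL, bitDepth = 16L) {
  if (length(dim(frames)) == 3L)
    dim(frames) <- c(dim(frames), 1L)
  if (is.integer(frames) || max(frames, na.rm = TRUE) > 1 + 1e-9)
    frames <- frames / (2^bitDepth - 1)
  storage.mode(frames) <- "double"
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(frames)[4]))
  new("VideoSequence", frames = frames, frameRate = as.numeric(frameRate),
      pixelSize = as.numeric(pixelSize), channelNames = as.character(channelNames))
}

#' RectROI: rectangular region of interest
#'
#' 0-based, half-open pixel rectangle: columns \code{x0 <= x < x1},
#' rows \code{y0 <= y < y1}. Replaces interactive four-point GUI selection
#' with explicit coordinates.
#'
#' @slot x0,y0,x1,y1 integer pixel bounds.
#' @exportClass RectROI
setClass("RectROI", representation(x0 = "integer", y0 = "integer",
                                   x1 = "integer", y1 = "integer"))

setValidity("RectROI", function(object) {
  if (object@x0 < 0L || object@y0 < 0L) return("ROI coordinates must be >= 0")
  if (object@x0 >= object@x1 || object@y0 >= object@y1)
    return("ROI must satisfy x0 < x1 and y0 < y1")
  TRUE
})

#' @rdname RectROI-class
#' @param x0,y0 inclusive top-left corner (0-based).
#' @param x1,y1 exclusive bottom-right corner.
#' @return a \linkS4class{RectROI}.
#' @export
rectROI <- function(x0, y0, x1, y1)
  new("RectROI", x0 = as.integer(x0), y0 = as.integer(y0),
      x1 = as.integer(x1), y1 = as.integer(y1))

#' EdgeMask: edge-pixel subset of the temporal-mean image
#'
#' Boolean mask of pixels whose spatial gradient of the temporal-mean image
#' exceeds the gradient threshold in every analyzed channel; spectral
#' analysis is restricted to these pixels.
#'
#' @slot mask logical \code{H x W} matrix.
#' @slot meanImage numeric \code{H x W x C} temporal-mean image.
#' @slot gth gradient threshold (on normalized intensities).
#' @slot method edge operator used.
#' @slot window integer length-2 half-open frame window \code{[t0, t1)}.
#' @exportClass EdgeMask
setClass("EdgeMask",
  representation(mask = "matrix", meanImage = "array", gth = "numeric",
                 method = "character", window = "integer"))

setValidity("EdgeMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (!identical(dim(object@mask), dim(object@meanImage)[1:2]))
    return("mask and meanImage dimensions disagree")
  TRUE
})

#' PowerSpectrum: averaged Blackman-Tukey motion power spectrum
#'
#' One-sided power spectrum of edge-pixel intensity series, averaged over
#' the \code{M} edge pixels, with the dominant (non-DC) frequency annotated.
#'
#' @slot freqs frequency grid in Hz, from 0 to Nyquist.
#' @slot power nonnegative averaged spectral power.
#' @slot L autocorrelation subseries length used.
#' @slot M number of edge pixels averaged.
#' @slot dominantFreq argmax frequency excluding the DC bin, Hz.
#' @slot dominantProminence dominant peak height as percent above the mean
#'   non-DC power.
#' @slot frameRate sampling rate of the analyzed video, Hz.
#' @slot channel channel index (1-based) the spectrum was computed on.
#' @exportClass PowerSpectrum
setClass("PowerSpectrum",
  representation(freqs = "numeric", power = "numeric", L = "integer",
                 M = "integer", dominantFreq = "numeric",
                 dominantProminence = "numeric", frameRate = "numeric",
                 channel = "integer"))

setValidity("PowerSpectrum", function(object) {
  if (length(object@freqs) != length(object@power))
    return("freqs and power must have equal length")
  if (any(object@power < 0)) return("power must be nonnegative")
  if (object@freqs[1] != 0) return("first frequency bin must be DC")
  TRUE
})

#' PSFModel: microscope point spread function
#'
#' @slot kernel odd-sized square nonnegative kernel summing to 1.
#' @slot provenance \code{"user-supplied"} or \code{"blind-estimated"}.
#' @exportClass PSFModel
setClass("PSFModel",
  representation(kernel = "matrix", provenance = "character"))

setValidity("PSFModel", function(object) {
  k <- object@kernel
  if (nrow(k) != ncol(k) || nrow(k) %% 2 == 0)
    return("PSF kernel must be square with odd size")
  if (any(k < 0)) return("PSF kernel must be nonnegative")
  if (abs(sum(k) - 1) > 1e-9) return("PSF kernel must sum to 1")
  if (!object@provenance %in% c("user-supplied", "blind-estimated"))
    return("provenance must be 'user-supplied' or 'blind-estimated'")
  TRUE
})

#' @rdname PSFModel-class
#' @param kernel square odd-sized nonnegative matrix; normalized to sum 1.
#' @param provenance origin label.
#' @return a \linkS4class{PSFModel}.
#' @export
psfModel <- function(kernel, provenance = "user-supplied") {
  kernel <- kernel / sum(kernel)
  new("PSFModel", kernel = kernel, provenance = provenance)
}

#' StabilizationResult: stabilized video plus per-frame transforms
#'
#' @slot video stabilized \linkS4class{VideoSequence}.
#' @slot transforms data.frame with columns \code{frame, dx, dy, rot_deg,
#'   scale}: the similarity transform mapping each frame onto the reference.
#' @slot residual numeric length \code{T-1}: residual global translation
#'   (pixels) between consecutive stabilized frames.
#' @slot reference reference frame index (1-based).
#' @exportClass StabilizationResult
setClass("StabilizationResult",
  representation(video = "VideoSequence", transforms = "data.frame",
                 residual = "numeric", reference = "integer"))

#' MagnificationParams: phase-based magnification settings
#'
#' @slot alpha amplification factor (>= 0); small phase displacements are
#'   scaled by \code{1 + alpha}.
#' @slot centerFreq frequency to amplify, Hz.
#' @slot halfBand temporal band half-width, Hz.
#' @slot levels pyramid depth.
#' @slot orientations number of orientation bands.
#' @slot sigmaSpatial amplitude-weighted spatial phase-smoothing sigma in
#'   pixels (0 disables).
#' @exportClass MagnificationParams
setClass("MagnificationParams",
  representation(alpha = "numeric", centerFreq = "numeric",
                 halfBand = "numeric", levels = "integer",
                 orientations = "integer", sigmaSpatial = "numeric"))

setValidity("MagnificationParams", function(object) {
  msg <- character()
  if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
  if (object@centerFreq - object@halfBand <= 0)
    msg <- c(msg, "band must not reach down to DC (centerFreq - halfBand > 0)")
  if (object@levels < 1L) msg <- c(msg, "levels must be >= 1")
  if (object@orientations < 1L) msg <- c(msg, "orientations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname MagnificationParams-class
#' @param alpha amplification factor.
#' @param centerFreq frequency to amplify (Hz).
#' @param halfBand band half-width (Hz); default
#'   \code{0.1 * centerFreq}.
#' @param levels,orientations pyramid geometry.
#' @param sigmaSpatial phase smoothing sigma (px); 0 disables.
#' @return a \linkS4class{MagnificationParams}.
#' @export
magnificationParams <- function(alpha, centerFreq,
                                halfBand = 0.1 * centerFreq,
                                levels = 4L, orientations = 4L,
                                sigmaSpatial = 2) {
  new("MagnificationParams", alpha = as.numeric(alpha),
      centerFreq = as.numeric(centerFreq), halfBand = as.numeric(halfBand),
      levels = as.integer(levels), orientations = as.integer(orientations),
      sigmaSpatial = as.numeric(sigmaSpatial))
}

#' MotionGrid: one-pixel-wide grid line segments for motion detection
#'
#' Horizontal segments occupy \code{l*m < x < l*(m+1)}, \code{y = l*n};
#' vertical segments \code{x = l*m}, \code{l*n < y < l*(n+1)} (0-based,
#' strict inequalities, so each segment has \code{l - 1} interior pixels and
#' lattice corner pixels belong to no segment).
#'
#' @slot l odd segment length parameter (pixels).
#' @slot segments list; each element has \code{pixels} (n x 2 matrix of
#'   0-based (x, y)), \code{center} (0-based (x, y) of the mid-length pixel)
#'   and \code{orientation} ("h" or "v").
#' @slot dim image dimension \code{c(H, W)}.
#' @exportClass MotionGrid
setClass("MotionGrid",
  representation(l = "integer", segments = "list", dim = "integer"))

#' MotionDirector: a grid segment with significant motion and its direction
#'
#' @slot center 0-based (x, y) of the triggering segment's center pixel.
#' @slot thetaDeg assigned direction: 0, 45, 90 or 135 degrees measured
#'   from the image vertical (Y) axis.
#' @slot scores named rms center-of-mass amplitudes for the four probes.
#' @slot motionSum the summed absolute consecutive-frame intensity
#'   difference over the segment.
#' @slot l probe line length (pixels).
#' @exportClass MotionDirector
setClass("MotionDirector",
  representation(center = "numeric", thetaDeg = "numeric",
                 scores = "numeric", motionSum = "numeric", l = "integer"))

#' PhasedKymograph: probe-line kymograph with expansion/contraction labels
#'
#' @slot image \code{l x T} intensity kymograph along the probe line.
#' @slot cmTrack per-frame center-of-mass position (offset h, pixels).
#' @slot phaseSign per-frame sign of the fitted temporal derivative:
#'   +1 (positive derivative), -1, or 0.
#' @slot nFit half-window (frames) of the degree-5 polynomial fit.
#' @slot thetaDeg probe direction.
#' @slot center 0-based (x, y) probe center.
#' @exportClass PhasedKymograph
setClass("PhasedKymograph",
  representation(image = "matrix", cmTrack = "numeric",
                 phaseSign = "integer", nFit = "integer",
                 thetaDeg = "numeric", center = "numeric"))

#' MotionBudget: optic-flow degree of motion for one video
#'
#' @slot degreeOfMotion total flow magnitude summed over frame pairs and
#'   pixels.
#' @slot alpha amplification factor of the measured video (NA for raw).
#' @slot noiseThreshold Lucas-Kanade eigenvalue noise threshold.
#' @exportClass MotionBudget
setClass("MotionBudget",
  representation(degreeOfMotion = "numeric", alpha = "numeric",
                 noiseThreshold = "numeric"))

#' NoiseFloorCurve: degree of motion vs amplification, sample vs control
#'
#' @slot table data.frame with columns \code{alpha, control_motion,
#'   sample_motion, verdict}.
#' @exportClass NoiseFloorCurve
setClass("NoiseFloorCurve", representation(table = "data.frame"))

#' FixtureSpec: parameters of a synthetic fixture video
#'
#' The generator's defaults are the validation conditions used throughout:
#' a 128 x 128, 24 fps, 20 s clip, 1 Hz harmonic motion of 0.36 px
#' amplitude (the sub-pixel 1 um / 2.77 um-per-pixel stretch analog) with
#' additive Gaussian intensity noise of sigma 0.01.
#'
#' @slot kind "ring", "oscillating_texture", "drift" or "static".
#' @slot size image size \code{c(H, W)}.
#' @slot frames number of frames T.
#' @slot frameRate frames per second.
#' @slot motionFreq drive frequency, Hz.
#' @slot amplitudePx motion amplitude in pixels (sub-pixel allowed); for
#'   "drift" the per-frame velocity in px/frame.
#' @slot directionDeg translation direction, degrees from the image Y axis.
#' @slot noiseSigma additive Gaussian intensity noise sd.
#' @slot seed RNG seed; spec + seed determine the video byte-for-byte.
#' @slot radius ring rest radius r0 (ring kind only).
#' @slot allowAlias permit motionFreq above Nyquist (aliasing fixtures).
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(kind = "character", size = "integer", frames = "integer",
                 frameRate = "numeric", motionFreq = "numeric",
                 amplitudePx = "numeric", directionDeg = "numeric",
                 noiseSigma = "numeric", seed = "integer",
                 radius = "numeric", allowAlias = "logical"))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("ring", "oscillating_texture", "drift", "static"))
    msg <- c(msg, "unknown fixture kind")
  if (object@amplitudePx < 0) msg <- c(msg, "amplitudePx must be >= 0")
  if (!object@allowAlias && object@kind %in% c("ring", "oscillating_texture") &&
      object@motionFreq >= object@frameRate / 2)
    msg <- c(msg, "motionFreq at or above Nyquist (set allowAlias = TRUE to test aliasing)")
  if (length(msg)) msg else TRUE
})

#' @rdname FixtureSpec-class
#' @param kind fixture kind.
#' @param size \code{c(H, W)}.
#' @param frames frame count.
#' @param frameRate fps.
#' @param motionFreq drive frequency (Hz).
#' @param amplitudePx amplitude (px); drift velocity for kind "drift".
#' @param directionDeg motion direction (deg from the Y axis).
#' @param noiseSigma additive intensity noise sd.
#' @param seed RNG seed.
#' @param radius ring rest radius (px).
#' @param allowAlias allow super-Nyquist drive frequencies.
#' @return a \linkS4class{FixtureSpec}.
#' @export
fixtureSpec <- function(kind = c("ring", "oscillating_texture", "drift",
                                 "static"),
                        size = c(128L, 128L), frames = 480L, frameRate = 24,
                        motionFreq = 1, amplitudePx = 0.36,
                        directionDeg = 90, noiseSigma = 0.01, seed = 1L,
                        radius = min(size) / 4, allowAlias = FALSE) {
  kind <- match.arg(kind)
  new("FixtureSpec", kind = kind, size = as.integer(size),
      frames = as.integer(frames), frameRate = as.numeric(frameRate),
      motionFreq = as.numeric(motionFreq),
      amplitudePx = as.numeric(amplitudePx),
      directionDeg = as.numeric(directionDeg),
      noiseSigma = as.numeric(noiseSigma), seed = as.integer(seed),
      radius = as.numeric(radius), allowAlias = isTRUE(allowAlias))
}
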