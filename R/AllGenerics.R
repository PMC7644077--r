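#' @include AllClasses.R
NULL

#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @export
setGeneric("dominantFreq", function(x) standardGeneric("dominantFreq"))
#' @export
setGeneric("dominantPeriod", function(x) standardGeneric("dominantPeriod"))
#' @export
setGeneric("spectrumTable", function(x) standardGeneric("spectrumTable"))
#' @export
setGeneric("transforms", function(x) standardGeneric("transforms"))
#' @export
setGeneric("degreeOfMotionValue", function(x) standardGeneric("degreeOfMotionValue"))

#' Extract one frame as an H x W x C array
#' @param x a VideoSequence
#' @param t frame index, 1-based
#' @export
setGeneric("getFrame", function(x, t) standardGeneric("getFrame"))

#' Extract the intensity time series of one pixel
#' @param x a VideoSequence
#' @param px,py 0-based pixel coordinates (x = column, y = row)
#' @param channel channel index, 1-based
#' @export
setGeneric("pixelSeries", function(x, px, py, channel = 1L)
  standardGeneric("pixelSeries"))
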