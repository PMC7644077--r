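#' @include AllClasses.R
NULL

.metaPath <- function(path) paste0(path, ".meta.json")

#' Read a time-lapse video from a multi-page TIFF stack
#'
#' Reads a grayscale or multi-channel multi-page TIFF (one page per frame,
#' or \code{nz} z-planes per time point, of which one is selected) into a
#' \linkS4class{VideoSequence} with intensities normalized to \code{[0, 1]}.
#' TIFF carries no standard frame-rate tag, so the rate is taken from a
#' \code{<path>.meta.json} sidecar (written by \code{\link{writeVideo}})
#' unless overridden; with neither source available an error is raised,
#' since frequency analysis is meaningless without the frame rate.
#'
#' AVI/MP4 containers are not supported by this build; convert such videos
#' to multi-page TIFF first.
#'
#' @param path path to a .tif/.tiff file.
#' @param frameRate frames per second; overrides the sidecar when given.
#' @param pixelSize microns per pixel (metadata); overrides the sidecar.
#' @param nz number of z-planes interleaved per time point (default 1).
#' @param zIndex which z-plane to keep when \code{nz > 1} (1-based).
#' @return a \linkS4class{VideoSequence}.
#' @seealso \code{\link{writeVideo}}, \code{\link{cropROI}},
#'   \code{\link{selectChannels}}
#' @export
readVideo <- function(path, frameRate = NULL, pixelSize = NULL, nz = 1L,
                      zIndex = 1L) {
  if (!file.exists(path))
    stop("cannot read video: file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("avi", "mp4", "mov", "wmv"))
    stop("AVI/MP4 input is not supported by this build; ",
         "convert '", path, "' to a multi-page TIFF stack")
  if (!ext %in% c("tif", "tiff"))
    stop("unsupported video format '", ext, "' for file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("unreadable or corrupt TIFF file: ", path,
                           " (", conditionMessage(e), ")", call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (nz > 1L) {
    if (length(pages) %% nz != 0L)
      stop("page count ", length(pages), " is not a multiple of nz = ", nz)
    stopifnot(zIndex >= 1L, zIndex <= nz)
    pages <- pages[seq(zIndex, length(pages), by = nz)]
  }
  meta <- if (file.exists(.metaPath(path)))
    jsonlite::read_json(.metaPath(path), simplifyVector = TRUE) else list()
  if (is.null(frameRate)) frameRate <- meta$frame_rate_hz
  if (is.null(frameRate))
    stop("no frame rate available for '", path, "': pass frameRate= ",
         "(frequency analysis is meaningless without it)")
  if (is.null(pixelSize)) pixelSize <- meta$pixel_size_um
  if (is.null(pixelSize)) pixelSize <- NA_real_
  d1 <- dim(pages[[1]])
  C <- if (length(d1) == 3L) d1[3] else 1L
  Tn <- length(pages)
  fr <- array(0, dim = c(Tn, d1[1], d1[2], C))
  for (t in seq_len(Tn)) {
    p <- pages[[t]]
    if (!identical(dim(p)[1:2], d1[1:2]))
      stop("frame ", t, " has different dimensions in ", path)
    if (length(dim(p)) == 2L) dim(p) <- c(dim(p), 1L)
    fr[t, , , ] <- p
  }
  chn <- meta$channel_names
  if (is.null(chn) || length(chn) != C) chn <- NULL
  VideoSequence(fr, frameRate = frameRate, pixelSize = pixelSize,
                channelNames = chn)
}

#' Write a video to a multi-page TIFF stack
#'
#' Writes one TIFF page per frame at the requested bit depth (lossless up
#' to quantization: a write/read round trip reproduces intensities within
#' \code{1/(2^bitDepth - 1)}), plus a \code{<path>.meta.json} sidecar
#' carrying the frame rate, pixel size and channel names so that
#' \code{\link{readVideo}} can restore the full object.
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param path output .tif path.
#' @param format only \code{"tiff"} is supported in this build.
#' @param bitDepth 8 or 16 (default) bits per sample.
#' @return \code{path}, invisibly.
#' @export
writeVideo <- function(video, path, format = c("tiff", "mp4", "avi"),
                       bitDepth = 16L) {
  format <- match.arg(format)
  if (format != "tiff")
    stop("no ", toupper(format), " encoder is available in this build; ",
         "use format = 'tiff'")
  if (!dir.exists(dirname(path)))
    stop("cannot write video: directory does not exist: ", dirname(path))
  fr <- frames(video)
  Tn <- dim(fr)[1]
  pages <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    p <- fr[t, , , , drop = TRUE]
    pages[[t]] <- .clip01(p)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitDepth),
                  compression = "none", reduce = TRUE)
  jsonlite::write_json(
    list(frame_rate_hz = frameRate(video),
         pixel_size_um = pixelSize(video),
         channel_names = channelNames(video)),
    .metaPath(path), auto_unbox = TRUE, digits = NA, null = "null",
    na = "null")
  invisible(path)
}

#' Crop a rectangular region of interest out of every frame
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param roi a \linkS4class{RectROI} (0-based, half-open).
#' @return a \linkS4class{VideoSequence} of the cropped region with all
#'   metadata preserved.
#' @export
cropROI <- function(video, roi) {
  stopifnot(is(video, "VideoSequence"), is(roi, "RectROI"))
  d <- frameDim(video)
  if (roi@x1 > d[2] || roi@y1 > d[1])
    stop("ROI (", roi@x0, ",", roi@y0, ",", roi@x1, ",", roi@y1,
         ") exceeds frame bounds ", d[2], " x ", d[1], " (W x H)")
  fr <- video@frames[, (roi@y0 + 1L):roi@y1, (roi@x0 + 1L):roi@x1, ,
                     drop = FALSE]
  new("VideoSequence", frames = fr, frameRate = video@frameRate,
      pixelSize = video@pixelSize, channelNames = video@channelNames)
}

#' Keep a subset of channels, in the requested order
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param channels integer indices (1-based) or channel names.
#' @return a \linkS4class{VideoSequence} with only those channels.
#' @export
selectChannels <- function(video, channels) {
  stopifnot(is(video, "VideoSequence"))
  if (is.character(channels)) {
    idx <- match(channels, channelNames(video))
    if (anyNA(idx))
      stop("unknown channel(s) ",
           paste(channels[is.na(idx)], collapse = ", "),
           "; available: ", paste(channelNames(video), collapse = ", "))
  } else {
    idx <- as.integer(channels)
    if (any(idx < 1L) || any(idx > nChannels(video)))
      stop("channel index out of range; available: 1..", nChannels(video))
  }
  fr <- video@frames[, , , idx, drop = FALSE]
  new("VideoSequence", frames = fr, frameRate = video@frameRate,
      pixelSize = video@pixelSize,
      channelNames = channelNames(video)[idx])
}
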