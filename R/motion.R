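#' @include AllClasses.R utils.R
NULL

#' Build the motion-detection grid of one-pixel-wide line segments
#'
#' Enumerates all horizontal and vertical grid-line segments lying fully
#' inside an H x W frame. With the grid pitch \code{l} (odd), horizontal
#' segments occupy \code{l*m < x < l*(m+1)} at \code{y = l*n} and vertical
#' segments \code{l*n < y < l*(n+1)} at \code{x = l*m} (0-based, strict
#' inequalities): each segment holds \code{l - 1} interior pixels and
#' lattice corner pixels belong to no segment. The segment center is the
#' mid-length pixel (floor of the midpoint, a deterministic convention
#' since \code{l - 1} is even).
#'
#' @param shape image dimension \code{c(H, W)}.
#' @param l odd grid pitch, \code{3 <= l <= min(H, W)}.
#' @return a \linkS4class{MotionGrid}.
#' @export
buildGrid <- function(shape, l) {
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  l <- as.integer(l)
  if (l %% 2L == 0L) stop("grid pitch l must be odd")
  if (l < 3L || l > min(H, W))
    stop("grid pitch l must satisfy 3 <= l <= min(H, W) = ", min(H, W))
  segs <- list()
  half <- l %/% 2L
  ## horizontal segments: y = l*n, x in (l*m, l*(m+1))
  for (n in 0:((H - 1L) %/% l)) {
    y <- l * n
    for (m in 0:(W %/% l - 1L)) {
      xs <- (l * m + 1L):(l * (m + 1L) - 1L)
      if (max(xs) <= W - 1L)
        segs[[length(segs) + 1L]] <-
          list(pixels = cbind(x = xs, y = rep(y, l - 1L)),
               center = c(x = l * m + half, y = y), orientation = "h")
    }
  }
  ## vertical segments: x = l*m, y in (l*n, l*(n+1))
  for (m in 0:((W - 1L) %/% l)) {
    x <- l * m
    for (n in 0:(H %/% l - 1L)) {
      ys <- (l * n + 1L):(l * (n + 1L) - 1L)
      if (max(ys) <= H - 1L)
        segs[[length(segs) + 1L]] <-
          list(pixels = cbind(x = rep(x, l - 1L), y = ys),
               center = c(x = x, y = l * n + half), orientation = "v")
    }
  }
  new("MotionGrid", l = l, segments = segs, dim = c(H, W))
}

## per-pixel sum over frames of |I[t+1] - I[t]| for one channel
.temporalDiffMap <- function(video, channel = 1L) {
  fr <- video@frames[, , , channel]
  colSums(abs(fr[-1, , , drop = FALSE] - fr[-dim(fr)[1], , , drop = FALSE]),
          dims = 1)
}

#' Motion statistic per grid segment and thresholding
#'
#' For each grid segment, sums the absolute consecutive-frame intensity
#' differences over its pixels and all frame pairs; segments whose sum
#' exceeds the motion threshold \code{mth} are returned with their sums.
#' \code{mth} depends on the noise level of the (typically magnified)
#' video; \code{\link{autoMotionThreshold}} offers a reproducible default
#' from a static control region.
#'
#' @param video a single-channel-analyzed \linkS4class{VideoSequence}
#'   (typically the magnified output).
#' @param grid a \linkS4class{MotionGrid}.
#' @param mth motion threshold (>= 0).
#' @param channel channel to analyze.
#' @return list of segments (as in the grid) each augmented with
#'   \code{motionSum}.
#' @export
detectMovingSegments <- function(video, grid, mth, channel = 1L) {
  stopifnot(is(video, "VideoSequence"), is(grid, "MotionGrid"), mth >= 0)
  if (!identical(frameDim(video), grid@dim))
    stop("grid dimensions do not match the video")
  sums <- .segmentSums(video, grid, channel)
  out <- list()
  for (i in seq_along(grid@segments)) {
    if (sums[i] > mth) {
      seg <- grid@segments[[i]]
      seg$motionSum <- sums[i]
      out[[length(out) + 1L]] <- seg
    }
  }
  out
}

.segmentSums <- function(video, grid, channel = 1L) {
  dmap <- .temporalDiffMap(video, channel)
  vapply(grid@segments, function(seg)
    sum(dmap[cbind(seg$pixels[, "y"] + 1L, seg$pixels[, "x"] + 1L)]),
    numeric(1))
}

#' Motion threshold from a static control region
#'
#' Sets the motion threshold to the given quantile (default 95th
#' percentile) of the per-segment motion sums inside a user-designated
#' static control region: a reproducible stand-in for choosing the
#' threshold empirically against the noise level.
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param controlRoi a \linkS4class{RectROI} known to contain no motion.
#' @param l grid pitch.
#' @param probs quantile (default 0.95).
#' @param channel channel to analyze.
#' @return numeric threshold.
#' @export
autoMotionThreshold <- function(video, controlRoi, l, probs = 0.95,
                                channel = 1L) {
  ctrl <- cropROI(video, controlRoi)
  grid <- buildGrid(frameDim(ctrl), l)
  sums <- .segmentSums(ctrl, grid, channel)
  as.numeric(stats::quantile(sums, probs))
}

## pixel offsets of the four probe lines, h = -(l-1)/2 .. +(l-1)/2;
## theta measured from the image Y axis (0 = vertical), 45-degree probes
## run along 8-connected diagonal chains
.probeOffsets <- function(thetaDeg, l) {
  h <- (-(l - 1L) %/% 2L):((l - 1L) %/% 2L)
  switch(as.character(thetaDeg),
         "0" = cbind(dx = rep(0L, l), dy = h),
         "45" = cbind(dx = h, dy = h),
         "90" = cbind(dx = h, dy = rep(0L, l)),
         "135" = cbind(dx = h, dy = -h),
         stop("theta must be one of 0, 45, 90, 135"))
}

## Eq-6 center of mass of the probe line at every frame: T-vector of
## sum(h I) / sum(I) with a guard for vanishing total intensity
.cmTrack <- function(video, center, thetaDeg, l, channel = 1L) {
  off <- .probeOffsets(thetaDeg, l)
  h <- (-(l - 1L) %/% 2L):((l - 1L) %/% 2L)
  xs <- center[1] + off[, "dx"]; ys <- center[2] + off[, "dy"]
  d <- frameDim(video)
  if (any(xs < 0) || any(xs > d[2] - 1L) || any(ys < 0) || any(ys > d[1] - 1L))
    return(NULL)
  ## l x T intensity matrix along the probe
  prof <- vapply(seq_len(l), function(i)
    video@frames[, ys[i] + 1L, xs[i] + 1L, channel],
    numeric(nFrames(video)))
  tot <- rowSums(prof)
  cm <- as.vector(prof %*% h)
  ifelse(tot < 1e-12, 0, cm / ifelse(tot < 1e-12, 1, tot))
}

.thetaSet <- c(0, 45, 90, 135)

#' Assign the dominant motion direction of a grid segment
#'
#' Lays four one-pixel-wide probe lines of length \code{l} through the
#' segment's center, 45 degrees apart starting from the image vertical
#' (Y) axis, computes the gray-level center of mass of each probe at every
#' frame, and assigns the direction whose center-of-mass signal has the
#' largest rms amplitude about its temporal mean. Ties (measure-zero)
#' break toward the lowest angle.
#'
#' @param video a \linkS4class{VideoSequence} (typically magnified).
#' @param segment a grid segment (an element of
#'   \code{\link{detectMovingSegments}}'s result, or of a
#'   \linkS4class{MotionGrid}).
#' @param l probe length; defaults to the segment length + 1 (the grid
#'   pitch).
#' @param channel channel to analyze.
#' @return a \linkS4class{MotionDirector}, or \code{NULL} (with a warning)
#'   when a probe line leaves the frame.
#' @export
assignDirection <- function(video, segment, l = nrow(segment$pixels) + 1L,
                            channel = 1L) {
  l <- as.integer(l)
  center <- as.integer(segment$center)
  scores <- numeric(4)
  names(scores) <- paste0("rms", .thetaSet)
  for (i in seq_along(.thetaSet)) {
    cm <- .cmTrack(video, center, .thetaSet[i], l, channel)
    if (is.null(cm)) {
      warning("probe line leaves the frame for segment centered at (",
              center[1], ", ", center[2], "); segment skipped")
      return(NULL)
    }
    scores[i] <- sqrt(mean((cm - mean(cm))^2))
  }
  new("MotionDirector", center = as.numeric(center),
      thetaDeg = .thetaSet[which.max(scores)], scores = scores,
      motionSum = if (is.null(segment$motionSum)) NA_real_
                  else segment$motionSum,
      l = l)
}

#' Detect significant motion and assign directions in one call
#'
#' Runs \code{\link{detectMovingSegments}} and
#' \code{\link{assignDirection}} over a whole grid, suppressing segments
#' whose strongest probe rms is below a 1e-6 floor (no measurable
#' center-of-mass motion).
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param grid a \linkS4class{MotionGrid}.
#' @param mth motion threshold.
#' @param channel channel to analyze.
#' @return list of \linkS4class{MotionDirector}.
#' @export
findDirectors <- function(video, grid, mth, channel = 1L) {
  segs <- detectMovingSegments(video, grid, mth, channel)
  out <- list()
  for (seg in segs) {
    dir <- suppressWarnings(assignDirection(video, seg, channel = channel))
    if (!is.null(dir) && max(dir@scores) >= 1e-6)
      out[[length(out) + 1L]] <- dir
  }
  out
}

#' Directors as a data.frame
#'
#' @param directors list of \linkS4class{MotionDirector}.
#' @return data.frame with columns \code{cx, cy, theta_deg, rms0, rms45,
#'   rms90, rms135, motion_sum}.
#' @export
directorTable <- function(directors) {
  do.call(rbind, lapply(directors, function(d)
    data.frame(cx = d@center[1], cy = d@center[2], theta_deg = d@thetaDeg,
               rms0 = d@scores[1], rms45 = d@scores[2],
               rms90 = d@scores[3], rms135 = d@scores[4],
               motion_sum = d@motionSum, row.names = NULL)))
}

#' Kymograph with expansion/contraction phase labels
#'
#' Builds the y-t kymograph of the probe line through \code{center} along
#' \code{thetaDeg}, tracks the gray-level center of mass per frame, and
#' labels each frame's motion phase by the sign of the temporal derivative
#' of the center-of-mass signal. The derivative is taken analytically from
#' a degree-5 polynomial least-squares fitted over the \code{2*nFit + 1}
#' frames around each time point; the first and last \code{nFit} frames
#' reuse the nearest full window. By default positive derivatives map to
#' red and negative to blue in \code{\link{plotKymograph}}; the mapping is
#' a display option, the stored labels are signs.
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param director a \linkS4class{MotionDirector}; alternatively give
#'   \code{center}, \code{thetaDeg} and \code{l} explicitly.
#' @param nFit half-window of the polynomial fit (>= 3, so the window
#'   holds at least the 6 points a quintic needs).
#' @param center,thetaDeg,l probe-line specification when no director is
#'   given.
#' @param channel channel to analyze.
#' @return a \linkS4class{PhasedKymograph}.
#' @export
phaseAnnotate <- function(video, director = NULL, nFit = 5L, center = NULL,
                          thetaDeg = NULL, l = NULL, channel = 1L) {
  if (!is.null(director)) {
    stopifnot(is(director, "MotionDirector"))
    center <- director@center; thetaDeg <- director@thetaDeg
    l <- director@l
  }
  nFit <- as.integer(nFit)
  if (nFit < 3L) stop("nFit must be >= 3 (a quintic needs >= 6 points)")
  Tn <- nFrames(video)
  if (Tn < 2L * nFit + 1L)
    stop("video too short: need at least 2*nFit + 1 = ", 2L * nFit + 1L,
         " frames")
  cm <- .cmTrack(video, as.integer(center), thetaDeg, as.integer(l),
                 channel)
  if (is.null(cm)) stop("probe line leaves the frame")
  off <- .probeOffsets(thetaDeg, as.integer(l))
  xs <- center[1] + off[, "dx"]; ys <- center[2] + off[, "dy"]
  img <- t(vapply(seq_len(nrow(off)), function(i)
    video@frames[, ys[i] + 1L, xs[i] + 1L, channel], numeric(Tn)))
  deriv <- numeric(Tn)
  win <- 2L * nFit + 1L
  for (t in seq_len(Tn)) {
    lo <- min(max(1L, t - nFit), Tn - win + 1L)
    idx <- lo:(lo + win - 1L)
    tc <- idx - t                       # centered time
    fit <- stats::lm.fit(outer(tc, 0:5, "^"), cm[idx])
    deriv[t] <- fit$coefficients[2]     # d/dt at tc = 0
  }
  sg <- as.integer(sign(deriv))
  sg[abs(deriv) < 1e-12] <- 0L
  new("PhasedKymograph", image = img, cmTrack = cm, phaseSign = sg,
      nFit = nFit, thetaDeg = as.numeric(thetaDeg),
      center = as.numeric(center))
}

## Bresenham-ish line rasterization between 0-based endpoints
.linePixels <- function(x0, y0, x1, y1) {
  n <- max(abs(x1 - x0), abs(y1 - y0), 1)
  cbind(x = round(seq(x0, x1, length.out = n + 1)),
        y = round(seq(y0, y1, length.out = n + 1)))
}

#' Overlay motion-direction arrows on a video
#'
#' Draws, on every frame, an arrow glyph at each director's center along
#' its assigned direction, with length proportional to the director's rms
#' amplitude score (scaled so the strongest director gets a full-length
#' arrow).
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param directors list of \linkS4class{MotionDirector}.
#' @param out optional path: when given the annotated video is written as
#'   TIFF.
#' @param maxLen full arrow half-length in pixels (default 8).
#' @return the annotated \linkS4class{VideoSequence}, invisibly if
#'   \code{out} is given.
#' @export
renderDirectors <- function(video, directors, out = NULL, maxLen = 8) {
  fr <- video@frames
  d <- frameDim(video)
  if (length(directors)) {
    smax <- max(vapply(directors, function(x) max(x@scores), numeric(1)))
    for (dir in directors) {
      len <- maxLen * max(dir@scores) / max(smax, 1e-12)
      th <- dir@thetaDeg * pi / 180
      ux <- sin(th); uy <- cos(th)
      tip <- dir@center + len * c(ux, uy)
      tail <- dir@center - len * c(ux, uy)
      px <- .linePixels(tail[1], tail[2], tip[1], tip[2])
      ## arrow head: two short barbs at the tip
      for (s in c(-1, 1)) {
        bx <- tip[1] - 0.35 * len * (ux * 0.7 - s * uy * 0.7)
        by <- tip[2] - 0.35 * len * (uy * 0.7 + s * ux * 0.7)
        px <- rbind(px, .linePixels(tip[1], tip[2], bx, by))
      }
      keep <- px[, "x"] >= 0 & px[, "x"] < d[2] &
              px[, "y"] >= 0 & px[, "y"] < d[1]
      px <- px[keep, , drop = FALSE]
      for (ch in seq_len(nChannels(video)))
        for (t in seq_len(nFrames(video)))
          fr[cbind(t, px[, "y"] + 1L, px[, "x"] + 1L, ch)] <- 1
    }
  }
  ann <- new("VideoSequence", frames = fr, frameRate = video@frameRate,
             pixelSize = video@pixelSize, channelNames = video@channelNames)
  if (!is.null(out)) {
    writeVideo(ann, out)
    return(invisible(ann))
  }
  ann
}
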