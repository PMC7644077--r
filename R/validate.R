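#' @include AllClasses.R utils.R evm.R
NULL

## dense Lucas-Kanade flow between two frames over a 5x5 window;
## returns the per-pixel flow magnitude, zeroed where the structure
## tensor's smaller eigenvalue is below the noise threshold
.lkMagnitude <- function(f1, f2, noiseThreshold, r = 2L) {
  H <- nrow(f1); W <- ncol(f1)
  ## central-difference spatial gradients of the mean frame
  fm <- (f1 + f2) / 2
  gx <- (cbind(fm[, -1], fm[, W]) - cbind(fm[, 1], fm[, -W])) / 2
  gy <- (rbind(fm[-1, ], fm[H, ]) - rbind(fm[1, ], fm[-H, ])) / 2
  gt <- f2 - f1
  Sxx <- .boxSum(gx * gx, r); Sxy <- .boxSum(gx * gy, r)
  Syy <- .boxSum(gy * gy, r)
  Sxt <- .boxSum(gx * gt, r); Syt <- .boxSum(gy * gt, r)
  tr <- Sxx + Syy
  eigMin <- (tr - sqrt((Sxx - Syy)^2 + 4 * Sxy^2)) / 2
  det <- Sxx * Syy - Sxy^2
  ok <- eigMin > noiseThreshold & det > 1e-18
  det[!ok] <- 1
  u <- (-Syy * Sxt + Sxy * Syt) / det
  v <- (Sxy * Sxt - Sxx * Syt) / det
  mag <- sqrt(u^2 + v^2)
  mag[!ok] <- 0
  mag
}

#' Optic-flow degree of motion of a video
#'
#' Estimates dense Lucas-Kanade optic flow between every pair of
#' consecutive frames (5x5 windows, flow suppressed where the gradient
#' structure tensor's smaller eigenvalue falls below the noise-reduction
#' threshold) and sums the flow magnitude over all pixels and frame
#' pairs. This single scalar quantifies how much apparent movement a clip
#' contains, and is the yardstick for separating genuinely amplified
#' motion from amplified noise.
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param noiseThreshold eigenvalue threshold for noise reduction
#'   (default 1e-4).
#' @param channel channel to analyze.
#' @param alpha amplification factor of the measured video, carried as
#'   metadata.
#' @return a \linkS4class{MotionBudget}.
#' @export
degreeOfMotion <- function(video, noiseThreshold = 1e-4, channel = 1L,
                           alpha = NA_real_) {
  stopifnot(is(video, "VideoSequence"))
  Tn <- nFrames(video)
  if (Tn < 2L) stop("degree of motion needs at least 2 frames")
  total <- 0
  for (t in seq_len(Tn - 1L)) {
    f1 <- matrix(video@frames[t, , , channel], frameDim(video)[1])
    f2 <- matrix(video@frames[t + 1L, , , channel], frameDim(video)[1])
    total <- total + sum(.lkMagnitude(f1, f2, noiseThreshold))
  }
  new("MotionBudget", degreeOfMotion = total, alpha = as.numeric(alpha),
      noiseThreshold = as.numeric(noiseThreshold))
}

#' Noise-floor curve: degree of motion vs amplification factor
#'
#' Magnifies a sample video and a static control video at each
#' amplification factor and measures both degrees of motion. Amplified
#' noise grows with alpha too, so the control curve is the noise floor:
#' where the sample exceeds it, the amplified motion is judged real;
#' where it does not, the apparent motion is at noise level.
#'
#' @param sample \linkS4class{VideoSequence} under test.
#' @param control static-control \linkS4class{VideoSequence} (same frame
#'   rate, similar size).
#' @param alphas amplification factors to sweep.
#' @param params a \linkS4class{MagnificationParams} template; its alpha
#'   is replaced by each sweep value.
#' @param noiseThreshold flow noise threshold.
#' @return a \linkS4class{NoiseFloorCurve}.
#' @export
noiseFloorCurve <- function(sample, control, alphas, params,
                            noiseThreshold = 1e-4) {
  stopifnot(length(alphas) >= 1)
  if (abs(frameRate(sample) - frameRate(control)) > 1e-9)
    stop("sample and control frame rates differ")
  rows <- lapply(alphas, function(a) {
    p <- params; p@alpha <- as.numeric(a)
    sm <- degreeOfMotion(magnify(sample, p), noiseThreshold, alpha = a)
    cm <- degreeOfMotion(magnify(control, p), noiseThreshold, alpha = a)
    data.frame(alpha = a, control_motion = cm@degreeOfMotion,
               sample_motion = sm@degreeOfMotion,
               verdict = if (sm@degreeOfMotion > cm@degreeOfMotion)
                 "real" else "noise-level")
  })
  new("NoiseFloorCurve", table = do.call(rbind, rows))
}
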