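#' @include AllClasses.R utils.R
NULL

## seeded, band-limited random texture in [0.2, 0.8]; generated in the
## Fourier domain, hence periodic, so Fourier-shift translation is exact
.bandLimitedTexture <- function(H, W, cutoff = 0.15) {
  noise <- matrix(stats::rnorm(H * W), H, W)
  fy <- .fftFreq(H); fx <- .fftFreq(W)
  r2 <- outer(fy^2, rep(1, W)) + outer(rep(1, H), fx^2)
  filt <- exp(-r2 / cutoff^2)
  tex <- Re(.ifft2(.fft2(noise) * filt))
  tex <- tex - min(tex)
  0.2 + 0.6 * tex / max(tex)
}

.fixtureNoise <- function(fr, sigma) {
  if (sigma > 0)
    fr <- fr + array(stats::rnorm(length(fr), sd = sigma), dim = dim(fr))
  .clip01(fr)
}

.displacementSeries <- function(spec) {
  t <- 0:(spec@frames - 1)
  spec@amplitudePx * sin(2 * pi * spec@motionFreq * t / spec@frameRate)
}

.warnIfAliasing <- function(spec) {
  if (spec@motionFreq >= spec@frameRate / 2)
    warning(sprintf(paste0("motion frequency %g Hz is at or above Nyquist ",
                           "(%g Hz); it will alias to %g Hz"),
                    spec@motionFreq, spec@frameRate / 2,
                    aliasedFrequency(spec@motionFreq, spec@frameRate)),
            call. = FALSE)
}

#' Synthetic pulsating-ring video
#'
#' An anti-aliased bright ring on a dark background whose radius breathes
#' harmonically, \eqn{r(t) = r_0 + a \sin(2\pi f t)}: the geometric
#' stand-in for a cell rhythmically expanding and contracting. Ground
#' truth (the radius series) is returned alongside so downstream tests
#' assert recovery, not plausibility.
#'
#' @param spec a \linkS4class{FixtureSpec} with \code{kind = "ring"}.
#' @return list with \code{video} (a \linkS4class{VideoSequence}) and
#'   \code{truth} (data.frame: frame, time_s, radius_px).
#' @export
makeRing <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"), spec@kind == "ring")
  H <- spec@size[1]; W <- spec@size[2]
  ringWidth <- 1.2
  if (spec@radius + spec@amplitudePx + 3 * ringWidth > min(H, W) / 2 - 1)
    stop("ring leaves the frame at maximum radius; reduce radius or amplitude")
  .warnIfAliasing(spec)
  withSeed(spec@seed, {
    cx <- (W - 1) / 2; cy <- (H - 1) / 2
    dist <- sqrt(outer(((0:(H - 1)) - cy)^2, rep(1, W)) +
                   outer(rep(1, H), ((0:(W - 1)) - cx)^2))
    tt <- 0:(spec@frames - 1)
    radius <- spec@radius + .displacementSeries(spec)
    fr <- array(0, dim = c(spec@frames, H, W, 1))
    for (t in seq_len(spec@frames))
      fr[t, , , 1] <- 0.05 + 0.85 * exp(-(dist - radius[t])^2 /
                                          (2 * ringWidth^2))
    fr <- .fixtureNoise(fr, spec@noiseSigma)
    list(video = VideoSequence(fr, frameRate = spec@frameRate),
         truth = data.frame(frame = tt, time_s = tt / spec@frameRate,
                            radius_px = radius))
  })
}

#' Synthetic sub-pixel oscillating-texture video
#'
#' A fixed band-limited random texture translating as
#' \eqn{d(t) = a \sin(2\pi f t)} along a chosen direction, using Fourier
#' phase-shift interpolation so sub-pixel displacement is exact; additive
#' Gaussian noise is applied after the shift. With the default amplitude
#' of 0.36 px the motion is invisible frame-to-frame — the synthetic analog
#' of a cyclically stretched gel imaged at a pixel size larger than the
#' stretch amplitude.
#'
#' @param spec a \linkS4class{FixtureSpec} with
#'   \code{kind = "oscillating_texture"}.
#' @return list with \code{video} and \code{truth} (data.frame: frame,
#'   time_s, displacement_px, dx_px, dy_px).
#' @export
makeOscillatingTexture <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"), spec@kind == "oscillating_texture")
  .warnIfAliasing(spec)
  withSeed(spec@seed, {
    H <- spec@size[1]; W <- spec@size[2]
    tex <- .bandLimitedTexture(H, W)
    d <- .displacementSeries(spec)
    th <- spec@directionDeg * pi / 180
    dx <- d * sin(th); dy <- d * cos(th)
    fr <- array(0, dim = c(spec@frames, H, W, 1))
    for (t in seq_len(spec@frames))
      fr[t, , , 1] <- fourierShift(tex, dx[t], dy[t])
    fr <- .fixtureNoise(fr, spec@noiseSigma)
    tt <- 0:(spec@frames - 1)
    list(video = VideoSequence(fr, frameRate = spec@frameRate),
         truth = data.frame(frame = tt, time_s = tt / spec@frameRate,
                            displacement_px = d, dx_px = dx, dy_px = dy))
  })
}

#' Synthetic static control video
#'
#' A fixed texture plus per-frame iid Gaussian intensity noise and no
#' motion whatsoever: the control whose amplified "motion" is pure noise.
#'
#' @param spec a \linkS4class{FixtureSpec} with \code{kind = "static"}.
#' @return list with \code{video} and \code{truth} (all-zero displacement).
#' @export
makeStatic <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"), spec@kind == "static")
  withSeed(spec@seed, {
    H <- spec@size[1]; W <- spec@size[2]
    tex <- .bandLimitedTexture(H, W)
    fr <- array(rep(tex, each = spec@frames),
                dim = c(spec@frames, H, W, 1))
    fr <- .fixtureNoise(fr, spec@noiseSigma)
    tt <- 0:(spec@frames - 1)
    list(video = VideoSequence(fr, frameRate = spec@frameRate),
         truth = data.frame(frame = tt, time_s = tt / spec@frameRate,
                            displacement_px = 0))
  })
}

#' Synthetic constant-velocity drift video
#'
#' A texture translating at \code{amplitudePx} pixels per frame along
#' \code{directionDeg}: the stand-in for immersed-sample drift, used to
#' exercise video stabilization.
#'
#' @param spec a \linkS4class{FixtureSpec} with \code{kind = "drift"};
#'   \code{amplitudePx} is the velocity in px/frame.
#' @return list with \code{video} and \code{truth} (frame, time_s, dx_px,
#'   dy_px cumulative displacement).
#' @export
makeDrift <- function(spec) {
  stopifnot(is(spec, "FixtureSpec"), spec@kind == "drift")
  withSeed(spec@seed, {
    H <- spec@size[1]; W <- spec@size[2]
    tex <- .bandLimitedTexture(H, W)
    tt <- 0:(spec@frames - 1)
    th <- spec@directionDeg * pi / 180
    dx <- spec@amplitudePx * tt * sin(th)
    dy <- spec@amplitudePx * tt * cos(th)
    fr <- array(0, dim = c(spec@frames, H, W, 1))
    for (t in seq_len(spec@frames))
      fr[t, , , 1] <- fourierShift(tex, dx[t], dy[t])
    fr <- .fixtureNoise(fr, spec@noiseSigma)
    list(video = VideoSequence(fr, frameRate = spec@frameRate),
         truth = data.frame(frame = tt, time_s = tt / spec@frameRate,
                            dx_px = dx, dy_px = dy))
  })
}

#' Generate a fixture video from its spec
#'
#' Dispatches on \code{spec@kind}. Identical spec + seed yields a
#' bit-identical video.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @return list with \code{video} and \code{truth}.
#' @export
makeFixture <- function(spec) {
  switch(spec@kind,
         ring = makeRing(spec),
         oscillating_texture = makeOscillatingTexture(spec),
         static = makeStatic(spec),
         drift = makeDrift(spec))
}
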