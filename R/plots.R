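#' @include AllClasses.R
NULL

#' Plot a motion power spectrum
#'
#' Base-graphics line plot of power versus frequency with the dominant
#' non-DC peak marked.
#'
#' @param spec a \linkS4class{PowerSpectrum}.
#' @param logY plot power on a log scale (default TRUE).
#' @param ... passed to \code{plot}.
#' @export
plotSpectrum <- function(spec, logY = TRUE, ...) {
  stopifnot(is(spec, "PowerSpectrum"))
  f <- spec@freqs[-1]; p <- spec@power[-1]
  graphics::plot(f, p, type = "l", log = if (logY) "y" else "",
                 xlab = "frequency (Hz)", ylab = "power",
                 main = sprintf("dominant %.4g Hz (M = %d, L = %d)",
                                spec@dominantFreq, spec@M, spec@L), ...)
  graphics::abline(v = spec@dominantFreq, lty = 3, col = "red")
}

#' Plot a phase-annotated kymograph
#'
#' Renders the probe-line kymograph in gray with the center-of-mass track
#' overlaid, colored by motion phase. By default frames with a positive
#' temporal derivative of the center of mass are red and negative ones
#' blue; pass \code{positiveColor}/\code{negativeColor} to flip the
#' convention.
#'
#' @param kymo a \linkS4class{PhasedKymograph}.
#' @param positiveColor,negativeColor colors of the two phases.
#' @export
plotKymograph <- function(kymo, positiveColor = "red",
                          negativeColor = "blue") {
  stopifnot(is(kymo, "PhasedKymograph"))
  Tn <- ncol(kymo@image); L <- nrow(kymo@image)
  graphics::image(x = seq_len(Tn), y = seq_len(L) - (L + 1) / 2,
                  z = t(kymo@image), col = grDevices::gray.colors(256),
                  xlab = "frame", ylab = "position h (px)",
                  main = sprintf("kymograph along %g deg at (%d, %d)",
                                 kymo@thetaDeg, kymo@center[1],
                                 kymo@center[2]))
  cols <- ifelse(kymo@phaseSign > 0, positiveColor,
                 ifelse(kymo@phaseSign < 0, negativeColor, "gray"))
  graphics::points(seq_len(Tn), kymo@cmTrack, col = cols, pch = 20,
                   cex = 0.6)
}

#' Plot a noise-floor curve
#'
#' Degree of motion versus amplification factor for the sample and the
#' static control; the region at or below the control curve is
#' noise-level apparent motion.
#'
#' @param curve a \linkS4class{NoiseFloorCurve}.
#' @export
plotNoiseFloor <- function(curve) {
  stopifnot(is(curve, "NoiseFloorCurve"))
  tb <- curve@table
  rng <- range(c(tb$control_motion, tb$sample_motion))
  graphics::plot(tb$alpha, tb$sample_motion, type = "b", pch = 19,
                 ylim = rng, xlab = "amplification factor",
                 ylab = "degree of motion")
  graphics::lines(tb$alpha, tb$control_motion, type = "b", pch = 1,
                  lty = 2)
  graphics::legend("topleft", legend = c("sample", "static control"),
                   lty = c(1, 2), pch = c(19, 1), bty = "n")
}
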