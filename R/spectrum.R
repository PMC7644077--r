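#' @include AllClasses.R utils.R edges.R
NULL

#' Biased sample autocorrelation of one pixel series
#'
#' Computes \eqn{r[\tau] = (1/N) \sum_t \tilde x[t] \tilde x[t+\tau]} for
#' lags \eqn{\tau = 0 \dots L-1}, where \eqn{\tilde x} is the series with
#' its temporal mean removed. \code{r[0]} is the biased sample variance.
#' The biased (1/N) normalization is the one whose Fourier transform is a
#' nonnegative-definite spectrum estimate, the standard choice for
#' Blackman-Tukey estimation.
#'
#' @param series numeric intensity series of one edge pixel.
#' @param L number of lags to return (\code{1 <= L <= length(series)}).
#' @return numeric vector of length L, lags 0..L-1.
#' @export
pixelAutocorrelation <- function(series, L = length(series)) {
  N <- length(series)
  if (L < 1 || L > N)
    stop("lag length L must satisfy 1 <= L <= N (N = ", N, ")")
  x <- series - mean(series)
  vapply(0:(L - 1), function(tau)
    sum(x[seq_len(N - tau)] * x[seq_len(N - tau) + tau]) / N, numeric(1))
}

## autocorrelations (lags 0..L-1) for all columns of an N x M series
## matrix at once, via the Wiener-Khinchin relation on zero-padded FFTs
.autocorrMatrix <- function(X, L) {
  N <- nrow(X)
  X <- sweep(X, 2, colMeans(X))
  nfft <- 2^ceiling(log2(2 * N))
  Xp <- rbind(X, matrix(0, nfft - N, ncol(X)))
  P <- Mod(stats::mvfft(Xp))^2
  R <- Re(stats::mvfft(P, inverse = TRUE)) / nfft / N
  R[seq_len(L), , drop = FALSE]
}

## one-sided Blackman-Tukey symmetrization of lag-domain autocorrelations:
## S[k] = r[0] + 2 * sum_{tau=1}^{L-1} w[tau] r[tau] cos(2 pi k tau / L)
.btSpectrum <- function(R, w) {
  WR <- R * w
  S <- 2 * Re(stats::mvfft(WR))
  sweep(S, 2, WR[1, ], "-")
}

#' Estimate the motion power spectrum over edge pixels
#'
#' Blackman-Tukey power-spectrum estimation of the intensity time series
#' of every edge pixel: each series is mean-removed, its biased sample
#' autocorrelation truncated at lag length \code{L} (optionally Bartlett
#' tapered) and Fourier transformed, and the per-pixel spectra are averaged
#' over the \code{M} edge pixels, which shrinks the estimator variance as
#' \code{M} grows. Negative excursions of the rectangularly truncated
#' estimate are clipped to zero. The dominant oscillation frequency is the
#' global maximum of the averaged spectrum excluding the DC bin.
#'
#' Motion above the Nyquist frequency (\code{frameRate / 2}) aliases: a
#' drive at \eqn{f_0} is reported at
#' \eqn{|f_0 - frameRate \cdot round(f_0 / frameRate)|}.
#'
#' @param video a \linkS4class{VideoSequence}.
#' @param edgeMask an \linkS4class{EdgeMask} from \code{\link{detectEdges}}.
#' @param L autocorrelation subseries length (default \code{N}, the frame
#'   count); shorter L trades frequency resolution for stability when the
#'   cell changes its motion frequency over time.
#' @param channel channel to analyze (1-based); channels are analyzed
#'   independently.
#' @param taper \code{"none"} (rectangular truncation, default) or
#'   \code{"bartlett"}.
#' @return a \linkS4class{PowerSpectrum} on the one-sided grid
#'   \code{f_k = k * frameRate / L}, \code{k = 0..floor(L/2)}.
#' @export
estimateSpectrum <- function(video, edgeMask, L = NULL, channel = 1L,
                             taper = c("none", "bartlett")) {
  taper <- match.arg(taper)
  stopifnot(is(video, "VideoSequence"), is(edgeMask, "EdgeMask"))
  d <- frameDim(video)
  if (!identical(dim(edgeMask@mask), d))
    stop("edge mask dimensions do not match the video")
  N <- nFrames(video)
  if (is.null(L)) L <- N
  L <- as.integer(L)
  if (L < 2L || L > N)
    stop("lag length L must satisfy 2 <= L <= N (N = ", N, ")")
  idx <- which(edgeMask@mask)
  M <- length(idx)
  if (M == 0L)
    stop("no edge pixels; lower gth")
  ## series matrix: frames are stored t-fastest, so a T x (H*W) reshape
  ## puts each pixel's series in one column
  X <- matrix(video@frames[, , , channel], nrow = N)[, idx, drop = FALSE]
  R <- .autocorrMatrix(X, L)
  w <- if (taper == "bartlett") 1 - (0:(L - 1)) / L else rep(1, L)
  S <- .btSpectrum(R, w)
  power <- rowMeans(S)[seq_len(L %/% 2 + 1L)]
  power[power < 0] <- 0
  freqs <- (0:(L %/% 2)) * frameRate(video) / L
  .newPowerSpectrum(freqs, power, L = L, M = M,
                    frameRate = frameRate(video), channel = channel)
}

.newPowerSpectrum <- function(freqs, power, L, M, frameRate, channel = 1L) {
  nonDC <- power[-1]
  kmax <- which.max(nonDC)
  dom <- freqs[-1][kmax]
  pbar <- mean(nonDC)
  prom <- if (length(nonDC) >= 3 && pbar > 0)
    100 * (nonDC[kmax] - pbar) / pbar else NA_real_
  new("PowerSpectrum", freqs = as.numeric(freqs), power = as.numeric(power),
      L = as.integer(L), M = as.integer(M), dominantFreq = dom,
      dominantProminence = prom, frameRate = as.numeric(frameRate),
      channel = as.integer(channel))
}

#' Construct a PowerSpectrum from a frequency/power table
#'
#' Convenience constructor (e.g. for re-analyzing an exported spectrum):
#' annotates the dominant non-DC frequency and its prominence.
#'
#' @param freqs frequency grid in Hz starting at 0.
#' @param power nonnegative power values.
#' @param frameRate sampling rate in Hz; default twice the maximum
#'   frequency.
#' @param M number of pixels the spectrum was averaged over.
#' @return a \linkS4class{PowerSpectrum}.
#' @export
powerSpectrum <- function(freqs, power, frameRate = 2 * max(freqs), M = 1L) {
  .newPowerSpectrum(freqs, power, L = length(freqs), M = M,
                    frameRate = frameRate)
}

#' Prominence of the dominant spectral peak
#'
#' Returns \code{100 * (P_dom - Pbar) / Pbar}, the dominant non-DC peak
#' height as percent above the mean non-DC power: a scalar measure of how
#' distinguished the dominant oscillation is from the spectral background
#' (live cells typically score markedly higher than fixated controls).
#'
#' @param spec a \linkS4class{PowerSpectrum} with at least 3 non-DC bins.
#' @return percent above mean non-DC power.
#' @export
dominantPeakProminence <- function(spec) {
  stopifnot(is(spec, "PowerSpectrum"))
  nonDC <- spec@power[-1]
  if (length(nonDC) < 3)
    stop("need at least 3 non-DC bins to measure prominence")
  pbar <- mean(nonDC)
  if (pbar == 0)
    stop("degenerate flat spectrum: mean non-DC power is zero")
  100 * (max(nonDC) - pbar) / pbar
}

#' Frequency an out-of-band drive aliases to
#'
#' @param f0 true motion frequency (Hz).
#' @param frameRate sampling rate (Hz).
#' @return the apparent (aliased) frequency in \code{[0, frameRate/2]}.
#' @export
aliasedFrequency <- function(f0, frameRate)
  abs(f0 - frameRate * round(f0 / frameRate))
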