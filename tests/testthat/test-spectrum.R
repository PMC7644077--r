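test_that("autocorrelation matches the brute-force double-loop oracle", {
  set.seed(21)
  x <- runif(16)
  r <- pixelAutocorrelation(x, 16)
  expect_equal(r, btOracleSpectrum(x, 16)$r, tolerance = 1e-12)
  # r[0] is the biased sample variance
  expect_equal(r[1], mean((x - mean(x))^2), tolerance = 1e-12)
  # constant series: all lags zero after mean removal
  expect_equal(pixelAutocorrelation(rep(0.7, 20), 10), rep(0, 10))
  # cosine anticorrelates at half period
  xc <- cos(2 * pi * (0:63) / 8)
  expect_lt(pixelAutocorrelation(xc, 8)[5], 0)
  expect_error(pixelAutocorrelation(x, 17), "L must satisfy")
})

test_that("single-pixel spectrum equals the DFT of the oracle autocorrelation", {
  set.seed(22)
  arr <- array(runif(32 * 16 * 16), dim = c(32, 16, 16, 1))
  v <- VideoSequence(arr, frameRate = 16)
  mask <- matrix(FALSE, 16, 16); mask[5, 7] <- TRUE
  em <- new("EdgeMask", mask = mask, meanImage = temporalMean(v),
            gth = 0, method = "sobel", window = c(0L, 32L))
  for (L in c(32L, 20L)) {
    sp <- estimateSpectrum(v, em, L = L)
    oracle <- btOracleSpectrum(arr[, 5, 7, 1], L)
    expect_equal(sp@power, oracle$power, tolerance = 1e-9)
    expect_equal(sp@freqs, (0:(L %/% 2)) * 16 / L)
  }
})

test_that("averaged spectrum is the pixel mean and its variance shrinks with M", {
  set.seed(23)
  arr <- array(runif(24 * 16 * 16), dim = c(24, 16, 16, 1))
  v <- VideoSequence(arr, frameRate = 12)
  maskAll <- matrix(TRUE, 16, 16)
  emAll <- new("EdgeMask", mask = maskAll, meanImage = temporalMean(v),
               gth = 0, method = "sobel", window = c(0L, 24L))
  spAll <- estimateSpectrum(v, emAll)
  perPixel <- sapply(which(maskAll), function(i) {
    btOracleSpectrum(matrix(arr[, , , 1], nrow = 24)[, i])$raw
  })
  expect_equal(spAll@power, pmax(rowMeans(perPixel), 0), tolerance = 1e-9)
  expect_equal(spAll@M, 256L)
  # empirical estimator variance across noise realizations: M = 64 pixels
  # vs M = 1, at a fixed non-DC bin
  varAt <- function(M) {
    mask <- matrix(FALSE, 16, 16); mask[seq_len(M)] <- TRUE
    vals <- vapply(1:10, function(s) {
      set.seed(100 + s)
      a <- array(rnorm(24 * 16 * 16, 0.5, 0.05), dim = c(24, 16, 16, 1))
      vv <- VideoSequence(pmin(pmax(a, 0), 1), frameRate = 12)
      e <- new("EdgeMask", mask = mask, meanImage = temporalMean(vv),
               gth = 0, method = "sobel", window = c(0L, 24L))
      estimateSpectrum(vv, e)@power[6]
    }, numeric(1))
    var(vals)
  }
  expect_lt(varAt(64), varAt(1))
})

test_that("sub-pixel 1 Hz oscillation is recovered within one frequency bin", {
  for (seed in 1:5) {
    fx <- makeOscillatingTexture(fixtureSpec("oscillating_texture",
                                             size = c(64, 64), frames = 240,
                                             frameRate = 24, motionFreq = 1,
                                             amplitudePx = 0.36,
                                             noiseSigma = 0.01,
                                             seed = seed))
    em <- detectEdges(fx$video, gth = 0.05, method = "sobel")
    sp <- estimateSpectrum(fx$video, em)
    expect_lt(abs(dominantFreq(sp) - 1), 24 / 240 + 1e-9)
  }
})

test_that("a static noisy video shows no dominant spectral peak", {
  fx <- makeStatic(fixtureSpec("static", size = c(64, 64), frames = 240,
                               frameRate = 24, noiseSigma = 0.01,
                               seed = 31))
  em <- detectEdges(fx$video, gth = 0.05, method = "sobel")
  sp <- estimateSpectrum(fx$video, em)
  nonDC <- sp@power[-1]
  expect_lt(max(nonDC), 3 * mean(nonDC))
})

test_that("peak prominence follows its definition", {
  flat <- powerSpectrum(seq(0, 5, by = 0.5), c(3, rep(2, 10)))
  expect_equal(dominantPeakProminence(flat), 0)
  # one bin at twice the rest: 100 * (2p - pbar) / pbar with
  # pbar = (9 * 1 + 2) / 10
  pk <- powerSpectrum(seq(0, 5, by = 0.5), c(5, rep(1, 9), 2))
  expect_equal(dominantPeakProminence(pk), 100 * (2 - 1.1) / 1.1,
               tolerance = 1e-12)
  expect_error(dominantPeakProminence(
    powerSpectrum(seq(0, 5, by = 0.5), rep(0, 11))), "flat spectrum")
  # oscillating fixture more prominent than static control
  osc <- makeOscillatingTexture(fixtureSpec("oscillating_texture",
                                            size = c(48, 48), frames = 120,
                                            seed = 32))
  sta <- makeStatic(fixtureSpec("static", size = c(48, 48), frames = 120,
                                seed = 32))
  spO <- estimateSpectrum(osc$video, detectEdges(osc$video, 0.05))
  spS <- estimateSpectrum(sta$video, detectEdges(sta$video, 0.05))
  expect_gt(dominantPeakProminence(spO), dominantPeakProminence(spS))
})

test_that("super-Nyquist motion is reported at the aliased frequency", {
  expect_equal(aliasedFrequency(20, 24), 4)
  expect_equal(aliasedFrequency(13, 24), 11)
  spec <- fixtureSpec("oscillating_texture", size = c(48, 48), frames = 120,
                      frameRate = 24, motionFreq = 20, amplitudePx = 0.4,
                      noiseSigma = 0.005, seed = 33, allowAlias = TRUE)
  expect_warning(fx <- makeOscillatingTexture(spec), "alias")
  sp <- estimateSpectrum(fx$video, detectEdges(fx$video, 0.05))
  expect_lt(abs(dominantFreq(sp) - 4), 24 / 120 + 1e-9)
})

test_that("estimateSpectrum validates its inputs", {
  fx <- makeStatic(fixtureSpec("static", size = c(16, 16), frames = 8,
                               noiseSigma = 0.01, seed = 34))
  em <- detectEdges(fx$video, gth = 10)      # empty mask
  expect_error(estimateSpectrum(fx$video, em), "no edge pixels; lower gth")
  em2 <- detectEdges(fx$video, gth = 0)
  expect_error(estimateSpectrum(fx$video, em2, L = 9), "L must satisfy")
})
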